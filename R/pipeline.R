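# End-to-end "study-shaped" run: simulate (or read) volumes, preprocess,
# cross-validate, test by permutation, compare against the TIV-only rival,
# correlate, stratify, and render a structured report.

#' Configuration of a full analysis run
#'
#' Precedence is caller > defaults; every stochastic stage derives its seed
#' deterministically from `seed` so a run is reproducible end to end.
#'
#' @param cohort A [cohort_config()] for simulated input; ignored when
#'   `input_dir` is given.
#' @param input_dir Optional directory with `participants.tsv` and one NIfTI
#'   per subject (see [read_fixture()]).
#' @param mask_threshold Mean-GM threshold for [build_mask()].
#' @param smooth_fwhm_mm Smoothing FWHM applied by the pipeline.
#' @param covariate_modes Covariate-adjusted reruns of the leave-one-out
#'   analysis, subset of `"age_sex"`, `"age_sex_tiv"`.
#' @param leakage `"foldwise"` (leakage-safe, default) or `"paper"`
#'   (whole-sample residualization).
#' @param scheme `"loo"`, plus split-half cycles when `split_repeats > 0`.
#' @param split_counts Training subjects per group for split-half cycles.
#' @param split_repeats Number of split-half cycles.
#' @param n_perm Global permutation count (desk-scale default 999).
#' @param n_perm_map Voxelwise permutation count (desk-scale default 199).
#' @param C_effective Hard-margin box constraint.
#' @param tiv_C Box constraint of the TIV-only soft-margin classifier.
#' @param seed Master seed.
#' @param out_dir Optional output directory for TSV/NIfTI artifacts.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(cohort = cohort_config(),
                            input_dir = NULL,
                            mask_threshold = 0.1,
                            smooth_fwhm_mm = 6,
                            covariate_modes = c("age_sex", "age_sex_tiv"),
                            leakage = c("foldwise", "paper"),
                            scheme = "loo",
                            split_counts = c(37, 35),
                            split_repeats = 2,
                            n_perm = 999,
                            n_perm_map = 199,
                            C_effective = 1e8,
                            tiv_C = 1,
                            seed = 1L,
                            out_dir = NULL) {
  leakage <- match.arg(leakage)
  if (length(covariate_modes))
    covariate_modes <- match.arg(covariate_modes,
                                 c("age_sex", "age_sex_tiv"), several.ok = TRUE)
  stopifnot(mask_threshold >= 0, smooth_fwhm_mm >= 0, n_perm >= 0,
            n_perm_map >= 0, length(split_counts) == 2L)
  structure(list(cohort = cohort, input_dir = input_dir,
                 mask_threshold = mask_threshold,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 covariate_modes = covariate_modes, leakage = leakage,
                 scheme = scheme, split_counts = split_counts,
                 split_repeats = split_repeats, n_perm = n_perm,
                 n_perm_map = n_perm_map, C_effective = C_effective,
                 tiv_C = tiv_C, seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

#' Run the full analysis pipeline
#'
#' Chains: simulate (or read) volumes -> smooth -> mask -> vectorize ->
#' leave-one-out SVM -> confusion metrics + ROC -> covariate-adjusted reruns
#' -> split-half cycles -> TIV-only classifier + DeLong comparison -> global
#' permutation test (accuracy and AUC) -> voxelwise weight p map ->
#' score-vs-clinical correlations -> WHO subgroup and SGA-excluded analyses.
#' When `config$out_dir` is set, TSV and NIfTI artifacts plus a plain-text
#' report are written there.
#'
#' @param config An [analysis_config()].
#' @return A `vbm_report` list holding every stage's result.
#' @export
run_pipeline <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$seed

  if (!is.null(config$input_dir)) {
    fx <- read_fixture(config$input_dir)
    volumes <- fx$volumes; table <- fx$table
  } else {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- seed
    cohort <- generate_cohort(cohort_cfg)
    volumes <- cohort$volumes; table <- cohort$table
  }
  labels <- as.integer(table$group)
  tiv <- compute_tiv(volumes)

  smoothed <- smooth_volumes(volumes, config$smooth_fwhm_mm)
  mask <- build_mask(smoothed, config$mask_threshold)
  features <- vectorize(smoothed, mask)

  cv <- loo_cv(features, labels, C_effective = config$C_effective)
  metrics <- confusion_metrics(cv)
  roc <- roc_curve(cv$score, labels)
  model <- train_linear_svm(features, labels, config$C_effective)

  adjusted <- list()
  for (mode in config$covariate_modes) {
    Z <- covariate_design(table, mode, tiv = tiv)
    # residualization projects the rows into a lower-rank space, where
    # hard-margin separability is no longer guaranteed; the adjusted reruns
    # therefore tolerate (and flag) margin violations
    cv_adj <- loo_cv(features, labels, C_effective = config$C_effective,
                     covariates = Z, leakage = config$leakage,
                     allow_violations = TRUE)
    adjusted[[mode]] <- list(cv = cv_adj, metrics = confusion_metrics(cv_adj),
                             leakage = config$leakage)
  }

  splits <- list()
  if (config$split_repeats > 0) {
    for (r in seq_len(config$split_repeats)) {
      splits[[r]] <- tryCatch({
        sh <- split_half_validation(features, labels,
                                    n_train_case = config$split_counts[1],
                                    n_train_control = config$split_counts[2],
                                    seed = seed + 1000L + r,
                                    C_effective = config$C_effective)
        list(cv = sh, metrics = confusion_metrics(sh))
      }, error = function(e) list(error = conditionMessage(e)))
    }
  }

  tiv_res <- tiv_only_classification(tiv, labels, C_effective = config$tiv_C)
  delong <- delong_compare(cv$score, tiv_res$cv$score, labels)

  perm <- NULL
  if (config$n_perm > 0)
    perm <- permute_global(features, labels, statistic = c("accuracy", "auc"),
                           n_perm = config$n_perm, seed = seed + 2000L,
                           C_effective = config$C_effective)
  pmap <- NULL
  if (config$n_perm_map > 0)
    pmap <- weight_pvalue_map(features, labels, n_perm = config$n_perm_map,
                              seed = seed + 3000L,
                              C_effective = config$C_effective, mask = mask)

  correlations <- rbind(
    correlate_scores(table, cv$score, c("ga_weeks", "bw_g"), subset = "cases"),
    correlate_scores(table, cv$score, "bw_g", subset = "controls"),
    correlate_scores(table, cv$score, c("iq_full", "iq_verbal", "iq_perf"),
                     subset = "all"),
    correlate_scores(table, cv$score, "iq_full", subset = "cases"))
  Ziq <- covariate_design(table, "age_sex_tiv", tiv = tiv)
  partial_iq <- lapply(c(iq_full = "iq_full", iq_verbal = "iq_verbal"),
                       function(v) tryCatch(partial_corr(cv$score, table[[v]], Ziq),
                                            error = function(e) NULL))

  subgroup <- who_stratify(table$ga_weeks, table$group)
  sub_means <- subgroup_mean_scores(cv$score[labels == 1L],
                                    subgroup[labels == 1L])
  pairwise <- list()
  for (pair in list(c("controls", "+2"), c("controls", "+3"), c("+2", "+3"))) {
    key <- paste(pair, collapse = "_vs_")
    pairwise[[key]] <- tryCatch({
      pcv <- pairwise_subgroup_classification(features, table, pair[1], pair[2],
                                              C_effective = config$C_effective)
      list(cv = pcv, metrics = confusion_metrics(pcv))
    }, error = function(e) list(error = conditionMessage(e)))
  }

  sga <- NULL
  if (any(table$group == 1 & !table$sga)) {
    scv <- sga_excluded_analysis(features, table,
                                 C_effective = config$C_effective)
    sga <- list(cv = scv, metrics = confusion_metrics(scv),
                n_excluded = attr(scv, "n_excluded"))
  }

  report <- structure(list(
    config = config, table = table, tiv = tiv, mask = mask, model = model,
    cv = cv, metrics = metrics, roc = roc, adjusted = adjusted,
    splits = splits, tiv_only = tiv_res, delong = delong, perm = perm,
    pmap = pmap, correlations = correlations, partial_iq = partial_iq,
    subgroup = subgroup, subgroup_means = sub_means, pairwise = pairwise,
    sga = sga), class = "vbm_report")

  if (!is.null(config$out_dir)) .write_report_artifacts(report, config$out_dir)
  report
}

.write_report_artifacts <- function(report, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create output directory: %s", out_dir),
                call. = FALSE)
  cfg <- report$config
  vs <- rep(1.5, 3)
  if (!is.null(cfg$cohort)) vs <- cfg$cohort$voxel_size_mm
  tsv <- function(df, name) write.table(df, file.path(out_dir, name),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE, na = "")
  scores <- report$cv
  scores$tiv_ml <- report$tiv
  tsv(scores, "decision_scores.tsv")
  tsv(report$correlations, "correlations.tsv")
  tsv(report$subgroup_means, "subgroup_means.tsv")
  tsv(report$roc$points, "roc_image.tsv")
  tsv(report$tiv_only$roc$points, "roc_tiv.tsv")
  if (!is.null(report$perm))
    tsv(data.frame(accuracy = report$perm$accuracy$null,
                   auc = report$perm$auc$null), "permutation_null.tsv")
  write_volume(weight_map(report$model, report$mask),
               file.path(out_dir, "weight_map.nii.gz"), vs)
  write_volume(array(as.numeric(report$mask), dim = dim(report$mask)),
               file.path(out_dir, "mask.nii.gz"), vs)
  if (!is.null(report$pmap))
    write_volume(report$pmap$p_volume, file.path(out_dir, "weight_pmap.nii.gz"), vs)
  writeLines(render_report(report), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Render a human-readable report of a pipeline run
#'
#' Every number carries its convention (p-value convention, sidedness,
#' residualization leakage mode); stages that were not run are listed as
#' "not run", never fabricated.
#'
#' @param report A `vbm_report` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "vbm_report"))
  fmt <- function(x, d = 4) formatC(x, digits = d, format = "f")
  m <- report$metrics
  lines <- c(
    "== Gray-matter SVM biomarker report ==",
    sprintf("seed %d | %d subjects (%d cases / %d controls) | %d masked voxels",
            report$config$seed, nrow(report$table),
            sum(report$table$group == 1), sum(report$table$group == -1),
            sum(report$mask)),
    "",
    "-- Leave-one-out classification (no covariates) --",
    sprintf("accuracy %s | sensitivity %s | specificity %s (TP %d FN %d TN %d FP %d)",
            fmt(m$accuracy), fmt(m$sensitivity), fmt(m$specificity),
            m$tp, m$fn, m$tn, m$fp),
    sprintf("decision-score AUC %s", fmt(report$roc$auc)))

  if (length(report$adjusted)) {
    lines <- c(lines, "", sprintf("-- Covariate-adjusted reruns (leakage mode: %s) --",
                                  report$config$leakage))
    for (mode in names(report$adjusted))
      lines <- c(lines, sprintf("%s: accuracy %s", mode,
                                fmt(report$adjusted[[mode]]$metrics$accuracy)))
  }
  if (length(report$splits)) {
    lines <- c(lines, "", sprintf("-- Split-half cycles (train %d/%d) --",
                                  report$config$split_counts[1],
                                  report$config$split_counts[2]))
    shown <- vapply(report$splits, function(s) {
      if (!is.null(s$error)) sprintf("not run (%s)", s$error)
      else fmt(s$metrics$accuracy, 3)
    }, character(1))
    lines <- c(lines, sprintf("held-out accuracies: %s",
                              paste(shown, collapse = ", ")))
  }

  d <- report$delong
  lines <- c(lines, "", "-- TIV-only rival classifier --",
             sprintf("TIV-only accuracy %s | AUC %s (soft margin, C = %g)",
                     fmt(confusion_metrics(report$tiv_only$cv)$accuracy),
                     fmt(report$tiv_only$auc), report$tiv_only$C_effective),
             sprintf("DeLong image vs TIV: dAUC %s, z %s, two-sided p %s%s",
                     fmt(d$auc_a - d$auc_b), fmt(d$z, 3),
                     format(d$p_value, digits = 3),
                     if (d$degenerate) " [degenerate variance]" else ""),
             sprintf("image AUC %s, %d%% CI [%s, %s]", fmt(d$auc_a),
                     round(100 * d$ci_level), fmt(d$ci_a[1]), fmt(d$ci_a[2])))

  lines <- c(lines, "", "-- Permutation inference --")
  if (is.null(report$perm)) {
    lines <- c(lines, "global permutation test: not run")
  } else {
    for (s in names(report$perm)) {
      pn <- report$perm[[s]]
      lines <- c(lines, sprintf("%s: observed %s, p = %s over %d permutations [(1+k)/(1+N); seed %d]",
                                s, fmt(pn$observed), format(pn$p_value, digits = 3),
                                pn$n_perm, pn$seed))
    }
  }
  if (is.null(report$pmap)) {
    lines <- c(lines, "voxelwise weight p map: not run")
  } else {
    lines <- c(lines, sprintf("voxel p map: %d permutations, two-sided on |w|, min p %s, %d voxels with p <= 0.05 (uncorrected)",
                              report$pmap$n_perm, format(min(report$pmap$p), digits = 3),
                              sum(report$pmap$p <= 0.05)))
  }

  lines <- c(lines, "", "-- Correlations with the decision score --")
  cr <- report$correlations
  for (i in seq_len(nrow(cr))) {
    lines <- c(lines, if (nzchar(cr$note[i]))
      sprintf("%s (%s): undefined (%s)", cr$variable[i], cr$subset[i], cr$note[i])
      else sprintf("%s (%s): r = %s, p = %s, n = %d", cr$variable[i],
                   cr$subset[i], fmt(cr$r[i], 3),
                   format(cr$p[i], digits = 3), cr$n[i]))
  }
  for (v in names(report$partial_iq)) {
    pc <- report$partial_iq[[v]]
    lines <- c(lines, if (is.null(pc))
      sprintf("%s | age+sex+TIV removed: not run", v)
      else sprintf("%s | age+sex+TIV removed: r = %s, p = %s (df %d)",
                   v, fmt(pc$r, 3), format(pc$p, digits = 3), pc$df))
  }

  lines <- c(lines, "", "-- WHO subgroups (cases) --")
  sm <- report$subgroup_means
  for (i in seq_len(nrow(sm)))
    lines <- c(lines, sprintf("%s (code %+d): n = %d, mean score %s",
                              sm$category[i], sm$code[i], sm$n[i],
                              fmt(sm$mean_score[i], 3)))
  for (key in names(report$pairwise)) {
    pw <- report$pairwise[[key]]
    lines <- c(lines, if (!is.null(pw$error))
      sprintf("%s: not run (%s)", key, pw$error)
      else sprintf("%s: accuracy %s", key, fmt(pw$metrics$accuracy, 3)))
  }

  lines <- c(lines, "", "-- SGA-excluded rerun --")
  lines <- c(lines, if (is.null(report$sga)) "not run (no non-SGA cases)"
             else sprintf("accuracy %s with %d SGA cases excluded",
                          fmt(report$sga$metrics$accuracy),
                          report$sga$n_excluded))
  lines
}

#' @export
print.vbm_report <- function(x, ...) {
  writeLines(render_report(x))
  invisible(x)
}
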