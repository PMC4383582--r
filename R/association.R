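# Correlation of the decision-score biomarker with clinical variables,
# WHO gestational-age stratification, and the SGA-excluded and TIV-only
# companion analyses.

#' Pearson correlation with a two-sided t-test p-value
#'
#' Pairs with missing values are dropped; at least 3 complete pairs are
#' required. Zero variance in either vector is an error (the correlation is
#' undefined), never a silent 0.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `r`, `p` (two-sided, from the t transform on `n - 2`
#'   degrees of freedom) and `n` (complete pairs used).
#' @export
pearson_corr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  r <- cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tt), n - 2), n = n)
}

#' Correlate decision scores with clinical variables
#'
#' One row per variable, with pairwise-complete missing-data handling and a
#' per-row `n`. An undefined correlation (zero variance) is surfaced in the
#' `note` column with a missing coefficient.
#'
#' @param table Participant table (columns as produced by
#'   [generate_cohort()]).
#' @param scores Per-subject decision scores aligned with `table` rows.
#' @param variables Subset of `ga_weeks`, `bw_g`, `iq_full`, `iq_verbal`,
#'   `iq_perf`.
#' @param subset `"all"`, `"cases"` or `"controls"`.
#' @return Data frame with columns variable, subset, n, r, p, note.
#' @export
correlate_scores <- function(table, scores,
                             variables = c("ga_weeks", "bw_g", "iq_full",
                                           "iq_verbal", "iq_perf"),
                             subset = c("all", "cases", "controls")) {
  subset <- match.arg(subset)
  variables <- match.arg(variables, several.ok = TRUE)
  stopifnot(length(scores) == nrow(table))
  rows <- switch(subset, all = seq_len(nrow(table)),
                 cases = which(table$group == 1),
                 controls = which(table$group == -1))
  if (!length(rows)) stop(sprintf("empty subset '%s'", subset), call. = FALSE)
  out <- lapply(variables, function(v) {
    res <- tryCatch(pearson_corr(scores[rows], table[[v]][rows]),
                    error = function(e) list(r = NA_real_, p = NA_real_,
                                             n = NA_integer_,
                                             note = conditionMessage(e)))
    data.frame(variable = v, subset = subset, n = res$n, r = res$r, p = res$p,
               note = res$note %||% "", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Partial correlation after covariate residualization
#'
#' Residualizes both the scores and the variable on the covariate design
#' (intercept included) through the residual-forming projection, then
#' computes the Pearson correlation of the residuals with degrees of freedom
#' reduced by the number of non-intercept covariate columns:
#' `df = n - 2 - k`.
#'
#' @param x,y Paired numeric vectors (e.g. decision scores and IQ).
#' @param covariates Covariate matrix, one row per subject; `NULL` or a
#'   zero-column matrix reduces to [pearson_corr()].
#' @return List with `r`, `p`, `n`, `df`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    res <- pearson_corr(x, y)
    return(c(res, list(df = res$n - 2)))
  }
  covariates <- as.matrix(covariates)
  keep <- is.finite(x) & is.finite(y) & apply(is.finite(covariates), 1, all)
  x <- x[keep]; y <- y[keep]
  Z <- covariates[keep, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  if (n - 2 - k < 1L) stop("too few complete observations for the design",
                           call. = FALSE)
  rz <- residualizer(.with_intercept(Z))
  rx <- drop(rz$R %*% x); ry <- drop(rz$R %*% y)
  if (sd(rx) < 1e-12 * max(sd(x), 1) || sd(ry) < 1e-12 * max(sd(y), 1))
    stop("undefined correlation: zero residual variance", call. = FALSE)
  r <- cor(rx, ry)
  df <- n - 2 - k
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tt), df), n = n, df = df)
}

.who_levels <- c("term", "moderately_preterm", "very_preterm", "extremely_preterm")
.who_codes <- c(term = -1, moderately_preterm = 1, very_preterm = 2,
                extremely_preterm = 3)

#' WHO gestational-age stratification
#'
#' Cases are banded by GA with half-open intervals: extremely preterm
#' (`GA < 28`), very preterm (`28 <= GA < 32`), moderately preterm
#' (`32 <= GA < 37`); controls are `term`. The numeric codes are +3, +2, +1
#' and -1 respectively (see [who_code()]). A case with `GA >= 37` is a
#' consistency error.
#'
#' @param ga_weeks Gestational age in weeks (continuous or completed).
#' @param group Group labels in `{-1, +1}`.
#' @return Factor with levels term, moderately_preterm, very_preterm,
#'   extremely_preterm.
#' @export
who_stratify <- function(ga_weeks, group) {
  stopifnot(length(ga_weeks) == length(group))
  if (any(!is.finite(ga_weeks))) stop("ga_weeks must be finite", call. = FALSE)
  bad <- group == 1 & ga_weeks >= 37
  if (any(bad))
    stop(sprintf("inconsistent table: case(s) with GA >= 37 weeks at rows %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  cat <- ifelse(group == -1, "term",
                ifelse(ga_weeks < 28, "extremely_preterm",
                       ifelse(ga_weeks < 32, "very_preterm", "moderately_preterm")))
  factor(cat, levels = .who_levels)
}

#' Numeric code of a WHO category
#'
#' @param category Factor or character as returned by [who_stratify()].
#' @return Numeric codes: term -1, moderately +1, very +2, extremely +3.
#' @export
who_code <- function(category) {
  unname(.who_codes[as.character(category)])
}

#' Mean decision score per WHO subgroup
#'
#' @param scores Decision scores.
#' @param subgroup Factor from [who_stratify()].
#' @return Data frame (category, code, n, mean_score); empty categories are
#'   absent, not zero.
#' @export
subgroup_mean_scores <- function(scores, subgroup) {
  stopifnot(length(scores) == length(subgroup))
  agg <- aggregate(list(mean_score = scores), by = list(category = subgroup),
                   FUN = mean, drop = TRUE)
  counts <- table(subgroup)
  agg$n <- as.integer(counts[as.character(agg$category)])
  agg$code <- who_code(agg$category)
  agg[order(agg$code), c("category", "code", "n", "mean_score")]
}

.select_subgroup <- function(table, spec) {
  cat <- who_stratify(table$ga_weeks, table$group)
  code <- who_code(cat)
  if (identical(spec, "controls") || identical(spec, -1)) return(which(code == -1))
  spec_num <- suppressWarnings(as.numeric(sub("^\\+", "", as.character(spec))))
  if (is.na(spec_num) || !spec_num %in% c(1, 2, 3))
    stop(sprintf("unknown subgroup '%s' (use 'controls', '+1', '+2' or '+3')",
                 as.character(spec)), call. = FALSE)
  which(code == spec_num)
}

#' Leave-one-out classification between two WHO-defined sets
#'
#' Restricts the cohort to two disjoint sets (`"controls"`, `"+1"`, `"+2"`,
#' `"+3"`), relabels the more-preterm set as `+1`, and runs the full
#' leave-one-out pipeline on those rows.
#'
#' @inheritParams loo_cv
#' @param table Participant table aligned with the feature rows.
#' @param set_a,set_b Subgroup specifiers; must not overlap.
#' @param ... Passed to [loo_cv()].
#' @return A `cv_result` restricted to the selected subjects.
#' @export
pairwise_subgroup_classification <- function(features, table, set_a, set_b, ...) {
  ia <- .select_subgroup(table, set_a)
  ib <- .select_subgroup(table, set_b)
  if (!length(ia) || !length(ib)) stop("empty subgroup selected", call. = FALSE)
  if (length(intersect(ia, ib)))
    stop("the two subgroups overlap", call. = FALSE)
  rank_of <- function(spec) if (identical(spec, "controls") || identical(spec, -1)) 0
    else as.numeric(sub("^\\+", "", as.character(spec)))
  # the more-preterm set is the positive class
  pos <- if (rank_of(set_a) >= rank_of(set_b)) ia else ib
  rows <- sort(c(ia, ib))
  y <- ifelse(rows %in% pos, 1L, -1L)
  cv <- loo_cv(as.matrix(features)[rows, , drop = FALSE], y, ...)
  attr(cv, "sets") <- list(set_a = set_a, set_b = set_b)
  cv
}

#' Leave-one-out classification excluding SGA-born cases
#'
#' Drops cases flagged small-for-gestational-age, keeps every control, and
#' reruns leave-one-out: if SGA subjects drove the original separation, the
#' accuracy should fall.
#'
#' @inheritParams pairwise_subgroup_classification
#' @return A `cv_result` over the retained subjects, with attribute
#'   `n_excluded`.
#' @export
sga_excluded_analysis <- function(features, table, ...) {
  keep <- !(table$group == 1 & table$sga)
  if (!any(table$group == 1 & !table$sga))
    stop("no non-SGA cases to analyze", call. = FALSE)
  cv <- loo_cv(as.matrix(features)[keep, , drop = FALSE],
               table$group[keep], ...)
  attr(cv, "n_excluded") <- sum(!keep)
  cv
}

#' Classification on the single feature of total intracranial volume
#'
#' Runs the same leave-one-out SVM machinery on a one-column feature matrix
#' of TIV. A single feature is rarely hard-margin separable, so this
#' operation always runs in the margin-violation-tolerant mode with a
#' moderate box constraint and flags it.
#'
#' @param tiv Per-subject TIV (ml).
#' @param labels Labels in `{-1, +1}`.
#' @param C_effective Moderate box constraint (default 1).
#' @param ... Passed to [loo_cv()].
#' @return List with `cv` (a `cv_result`), `roc` of the out-of-fold scores,
#'   `auc`, and `soft_margin = TRUE`.
#' @export
tiv_only_classification <- function(tiv, labels, C_effective = 1, ...) {
  tiv <- as.numeric(tiv)
  if (sd(tiv) == 0)
    stop("not separable: TIV is constant across subjects", call. = FALSE)
  X <- matrix(tiv, ncol = 1, dimnames = list(names(tiv), "tiv"))
  cv <- loo_cv(X, labels, C_effective = C_effective,
               allow_violations = TRUE, ...)
  roc <- roc_curve(cv$score, cv$label)
  list(cv = cv, roc = roc, auc = auc_mann_whitney(cv$score, cv$label),
       soft_margin = TRUE, C_effective = C_effective)
}
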