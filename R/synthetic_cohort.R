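# Synthetic case-control cohort generator.
#
# Emulates the statistical structure of a preterm-birth morphometry study:
# two groups of modulated gray-matter-like maps on a common grid, a spatially
# structured bidirectional group effect whose within-case expression follows
# a latent severity, a global-scale (TIV) confound correlated with group, GA
# and BW tied to severity, IQ negatively linked to severity, and an SGA
# subset whose severity is representative of the cases as a whole.

#' Default signed spherical effect regions
#'
#' Two positive and two negative spheres (voxel units) on the default 16^3
#' grid, giving the bidirectional weight pattern a preterm-vs-term gray-matter
#' classifier is expected to recover. The amplitude default is calibrated so
#' that an oracle readout along the true effect direction classifies a
#' default cohort with roughly 95% accuracy.
#'
#' @param amplitude Per-region amplitude in GM-map units.
#' @return List of regions, each `list(center, radius, sign, amplitude)`.
#' @export
default_effect_regions <- function(amplitude = 0.06) {
  list(
    list(center = c(8.5, 13, 8.5), radius = 2.6, sign = +1, amplitude = amplitude),
    list(center = c(8.5, 4, 8.5),  radius = 2.6, sign = +1, amplitude = amplitude),
    list(center = c(4.5, 8.5, 9),  radius = 2.4, sign = -1, amplitude = amplitude),
    list(center = c(12.5, 8.5, 9), radius = 2.4, sign = -1, amplitude = amplitude)
  )
}

#' Configuration of a synthetic cohort
#'
#' Defaults state the emulated study design: 74 cases and 69 controls; case
#' gestational age spanning 24-36 completed weeks (mean about 28.9) and
#' control GA 37-42; birth weight increasing with GA with cases capped at
#' 1500 g (the study's inclusion criterion); 22% of cases flagged small for
#' gestational age by drawing their BW-given-GA residual from the lowest
#' decile; IQ declining with severity; a modest global-scale gap between
#' groups standing in for the TIV confound; and spatially smoothed noise.
#'
#' @param n_case,n_control Group sizes (each `>= 2`).
#' @param grid_shape Integer length-3 grid.
#' @param voxel_size_mm Voxel size in mm.
#' @param effect_regions Signed spheres, see [default_effect_regions()].
#' @param effect_scale Global multiplier on region amplitudes; 0 gives a null
#'   cohort.
#' @param tiv_group_gap Fractional mean global-scale reduction in cases.
#' @param tiv_sd Within-group lognormal scale spread. Setting both `tiv_sd`
#'   and `tiv_group_gap` to 0 disables the global-scale machinery entirely
#'   (including its demographic sex/age components), leaving a pure
#'   voxel-noise null.
#' @param noise_sd Additive white-noise sd before smoothing (GM-map units).
#' @param smooth_fwhm_mm FWHM of the smoothing applied to the noise field.
#' @param severity_link Coefficients mapping latent severity in `[0,1]` to
#'   clinical variables: `ga = c(intercept, slope)` (weeks),
#'   `bw = c(intercept, slope_per_week)` (grams, against GA - 24 within
#'   cases), `iq = c(intercept, slope)` (points; negative slope gives the
#'   severity-IQ anticorrelation).
#' @param sga_fraction Fraction of cases flagged SGA.
#' @param iq_missing Probability a subject's IQ scores are missing.
#' @param seed RNG seed; generation is deterministic given the config.
#' @return A validated `cohort_config`.
#' @export
cohort_config <- function(n_case = 74, n_control = 69,
                          grid_shape = c(16L, 16L, 16L),
                          voxel_size_mm = c(1.5, 1.5, 1.5),
                          effect_regions = default_effect_regions(),
                          effect_scale = 1,
                          tiv_group_gap = 0.05,
                          tiv_sd = 0.06,
                          noise_sd = 0.05,
                          smooth_fwhm_mm = 6,
                          severity_link = list(ga = c(36, -12),
                                               bw = c(800, 50),
                                               iq = c(100, -12)),
                          sga_fraction = 16 / 74,
                          iq_missing = 0.15,
                          seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              grid_shape = as.integer(rep_len(grid_shape, 3L)),
              voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
              effect_regions = effect_regions, effect_scale = effect_scale,
              tiv_group_gap = tiv_group_gap, tiv_sd = tiv_sd,
              noise_sd = noise_sd, smooth_fwhm_mm = smooth_fwhm_mm,
              severity_link = severity_link, sga_fraction = sga_fraction,
              iq_missing = iq_missing, seed = as.integer(seed))
  if (cfg$n_case < 2L) .stop_field("n_case", "must be >= 2")
  if (cfg$n_control < 2L) .stop_field("n_control", "must be >= 2")
  if (any(cfg$grid_shape < 4L)) .stop_field("grid_shape", "axes must be >= 4 voxels")
  if (any(cfg$voxel_size_mm <= 0)) .stop_field("voxel_size_mm", "must be positive")
  if (cfg$smooth_fwhm_mm < 0) .stop_field("smooth_fwhm_mm", "must be >= 0")
  if (cfg$sga_fraction < 0 || cfg$sga_fraction > 1)
    .stop_field("sga_fraction", "must lie in [0, 1]")
  if (cfg$iq_missing < 0 || cfg$iq_missing > 1)
    .stop_field("iq_missing", "must lie in [0, 1]")
  if (cfg$noise_sd < 0) .stop_field("noise_sd", "must be >= 0")
  if (cfg$tiv_sd < 0) .stop_field("tiv_sd", "must be >= 0")
  .check_regions(cfg$grid_shape, cfg$effect_regions)
  for (nm in c("ga", "bw", "iq"))
    if (length(cfg$severity_link[[nm]]) != 2L)
      .stop_field("severity_link", sprintf("entry '%s' needs c(intercept, slope)", nm))
  structure(cfg, class = "cohort_config")
}

.check_regions <- function(grid_shape, regions) {
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (!all(c("center", "radius", "sign", "amplitude") %in% names(r)))
      .stop_field("effect_regions",
                  sprintf("region %d needs center, radius, sign, amplitude", i))
    if (!r$sign %in% c(-1, 1))
      .stop_field("effect_regions", sprintf("region %d sign must be -1 or +1", i))
    if (r$radius < 0 || r$amplitude < 0)
      .stop_field("effect_regions", sprintf("region %d radius/amplitude must be >= 0", i))
    if (any(r$center - r$radius < 1) || any(r$center + r$radius > grid_shape))
      .stop_field("effect_regions",
                  sprintf("region %d sphere extends outside the grid", i))
  }
  invisible(TRUE)
}

#' Build the signed effect map for a set of spherical regions
#'
#' Voxels inside a sphere carry `sign * amplitude`; overlapping spheres sum.
#'
#' @param grid_shape Integer length-3 grid.
#' @param effect_regions List of regions as in [cohort_config()].
#' @return A 3D array.
#' @export
make_effect_map <- function(grid_shape, effect_regions) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  .check_regions(grid_shape, effect_regions)
  eff <- array(0, dim = grid_shape)
  if (!length(effect_regions)) return(eff)
  co <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                    z = seq_len(grid_shape[3]))
  for (r in effect_regions) {
    d2 <- (co$x - r$center[1])^2 + (co$y - r$center[2])^2 + (co$z - r$center[3])^2
    eff <- eff + array(as.numeric(d2 <= r$radius^2), grid_shape) * r$sign * r$amplitude
  }
  eff
}

# smooth baseline "brain": ellipsoid with GM density rising toward the center
.baseline_template <- function(grid_shape) {
  c0 <- (grid_shape + 1) / 2
  semi <- 0.48 * grid_shape
  co <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                    z = seq_len(grid_shape[3]))
  r2 <- ((co$x - c0[1]) / semi[1])^2 + ((co$y - c0[2]) / semi[2])^2 +
    ((co$z - c0[3]) / semi[3])^2
  array(ifelse(r2 < 1, 0.25 + 0.35 * (1 - r2), 0), grid_shape)
}

#' Generate a synthetic cohort
#'
#' Case volumes are `scale_i * (template + severity_i * effect_map)` plus
#' spatially smoothed Gaussian noise, clipped at zero; control volumes carry
#' no effect (severity 0). The per-subject global scale is the true TIV
#' driver: it is reduced on average in cases by `tiv_group_gap`, is larger in
#' boys, declines slightly with age at scan, and varies lognormally within
#' group. GA, BW, IQ and the SGA flag follow the severity links of the
#' config. Output is deterministic given the config (which includes the
#' seed).
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: list with `volumes` ([gm_volume_set()]),
#'   `table` (participant data frame), and `truth` (per-subject latent
#'   severity and global scale, plus the true effect map).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  nc <- config$n_case; nk <- config$n_control; n <- nc + nk
  ids <- c(sprintf("case%03d", seq_len(nc)), sprintf("ctrl%03d", seq_len(nk)))
  group <- rep(c(1L, -1L), c(nc, nk))
  link <- config$severity_link

  # latent severity: Beta(2.8, 1.9) on [0,1] for cases; with the default GA
  # link this gives case GA mean ~28.9 w and WHO moderate/very/extreme
  # banding proportions close to 0.15/0.49/0.36
  severity <- c(rbeta(nc, 2.8, 1.9), rep(0, nk))
  ga <- numeric(n)
  ga[1:nc] <- link$ga[1] + link$ga[2] * severity[1:nc]
  ga[(nc + 1):n] <- 37 + 5 * rbeta(nk, 1.2, 1.0)

  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- pmin(pmax(rnorm(n, 14.6, 1.3), 12.2), 17.7)

  # tiv_sd = 0 together with tiv_group_gap = 0 switches the global-scale
  # machinery off entirely (including the demographic sex/age effects), so a
  # null cohort is driven by voxel noise alone
  if (config$tiv_sd > 0 || config$tiv_group_gap > 0) {
    scale <- (1 - config$tiv_group_gap * (group == 1L)) *
      (1 + 0.04 * (sex == "M")) * (1 - 0.01 * (age - 14.6)) *
      exp(rnorm(n, 0, config$tiv_sd))
  } else {
    scale <- rep(1, n)
  }

  # birth weight: linear growth in GA with Gaussian residual; SGA cases are
  # redrawn from the lowest decile of the residual distribution
  bw_resid <- c(rnorm(nc, 0, 150), rnorm(nk, 0, 350))
  sga <- rep(FALSE, n)
  n_sga <- round(config$sga_fraction * nc)
  if (n_sga > 0) {
    sga_idx <- sample(seq_len(nc), n_sga)
    sga[sga_idx] <- TRUE
    bw_resid[sga_idx] <- qnorm(runif(n_sga, 0, 0.10), 0, 150)
  }
  bw <- numeric(n)
  bw[1:nc] <- pmin(pmax(link$bw[1] + link$bw[2] * (ga[1:nc] - 24) +
                          bw_resid[1:nc], 500), 1500)
  bw[(nc + 1):n] <- pmin(pmax(2800 + 280 * (ga[(nc + 1):n] - 37) +
                                bw_resid[(nc + 1):n], 2500), 4700)

  iq_full <- link$iq[1] + link$iq[2] * severity + rnorm(n, 0, 11)
  iq_verbal <- link$iq[1] + 0.9 * link$iq[2] * severity + rnorm(n, 0, 12)
  iq_perf <- link$iq[1] + 0.8 * link$iq[2] * severity + rnorm(n, 0, 12)
  miss <- runif(n) < config$iq_missing
  iq_full[miss] <- NA_real_; iq_verbal[miss] <- NA_real_; iq_perf[miss] <- NA_real_

  template <- .baseline_template(config$grid_shape)
  eff <- config$effect_scale * make_effect_map(config$grid_shape, config$effect_regions)
  sigma_vox <- config$smooth_fwhm_mm /
    (config$voxel_size_mm * 2 * sqrt(2 * log(2)))
  vols <- vector("list", n)
  for (i in seq_len(n)) {
    noise <- array(rnorm(prod(config$grid_shape), 0, config$noise_sd),
                   config$grid_shape)
    if (config$smooth_fwhm_mm > 0) noise <- .smooth_array(noise, sigma_vox)
    vols[[i]] <- pmax(scale[i] * (template + severity[i] * eff) + noise, 0)
  }
  names(vols) <- ids

  table <- data.frame(
    id = ids, group = group, ga_weeks = ga,
    ga_completed = as.integer(floor(ga)), bw_g = bw, sex = sex, age_years = age,
    sga = sga, iq_full = iq_full, iq_verbal = iq_verbal, iq_perf = iq_perf,
    stringsAsFactors = FALSE)

  structure(list(
    volumes = gm_volume_set(vols, config$voxel_size_mm),
    table = table,
    truth = list(severity = stats::setNames(severity, ids),
                 scale = stats::setNames(scale, ids),
                 effect_map = eff, template = template),
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d cases / %d controls, grid %s\n",
              x$config$n_case, x$config$n_control,
              paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

#' Write a cohort to disk as NIfTI volumes plus TSV tables
#'
#' Writes one `.nii.gz` per subject, `participants.tsv`, the ground-truth
#' per-subject table `truth.tsv` (severity, global scale) and the true effect
#' map `effect_map.nii.gz`. The layout round-trips through [read_fixture()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create directory: %s", directory), call. = FALSE)
  vs <- cohort$volumes$voxel_size_mm
  vol_paths <- file.path(directory, paste0(cohort$volumes$subject_ids, ".nii.gz"))
  for (i in seq_along(vol_paths)) {
    tryCatch(nifti_write(cohort$volumes$data[[i]], vol_paths[i], vs,
                         cohort$volumes$affine),
             error = function(e) stop(sprintf("I/O error writing %s: %s",
                                              vol_paths[i], conditionMessage(e)),
                                      call. = FALSE))
  }
  tsv <- file.path(directory, "participants.tsv")
  write.table(cohort$table, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  truth_tsv <- file.path(directory, "truth.tsv")
  write.table(data.frame(id = names(cohort$truth$severity),
                         severity = cohort$truth$severity,
                         scale = cohort$truth$scale),
              truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  eff_path <- file.path(directory, "effect_map.nii.gz")
  nifti_write(cohort$truth$effect_map, eff_path, vs, cohort$volumes$affine,
              datatype = "float64")
  invisible(list(volumes = vol_paths, participants = tsv, truth = truth_tsv,
                 effect_map = eff_path))
}

#' Read a cohort fixture written by [write_fixture()] (or hand-assembled)
#'
#' Expects `participants.tsv` plus one `<id>.nii.gz` (or `.nii`) per row.
#'
#' @param directory Directory containing the fixture.
#' @return List with `volumes`, `table`, and `truth` (NULL when absent).
#' @export
read_fixture <- function(directory) {
  tsv <- file.path(directory, "participants.tsv")
  if (!file.exists(tsv))
    stop(sprintf("input file not found: %s", tsv), call. = FALSE)
  table <- read.delim(tsv, stringsAsFactors = FALSE)
  paths <- file.path(directory, paste0(table$id, ".nii.gz"))
  alt <- file.path(directory, paste0(table$id, ".nii"))
  paths[!file.exists(paths)] <- alt[!file.exists(paths)]
  volumes <- read_volumes(paths, subject_ids = table$id)
  truth <- NULL
  truth_tsv <- file.path(directory, "truth.tsv")
  if (file.exists(truth_tsv)) {
    tt <- read.delim(truth_tsv, stringsAsFactors = FALSE)
    truth <- list(severity = stats::setNames(tt$severity, tt$id),
                  scale = stats::setNames(tt$scale, tt$id))
    eff <- file.path(directory, "effect_map.nii.gz")
    if (file.exists(eff)) truth$effect_map <- nifti_read(eff)$data
  }
  list(volumes = volumes, table = table, truth = truth)
}
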