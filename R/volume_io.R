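# Volume container, smoothing, masking, TIV, vectorization and covariate
# removal: everything between raw modulated gray-matter maps and the feature
# matrix handed to the classifier.

#' Construct a gray-matter volume set
#'
#' A `gm_volume_set` holds one 3D volume per subject on a single common grid,
#' with a shared voxel size and affine. Mixed grids are rejected: volumes are
#' expected to have been spatially normalized upstream, and this container
#' never resamples.
#'
#' @param data Named list of 3D arrays, one per subject, identical dimensions.
#' @param voxel_size_mm Numeric length-3 voxel spacing in mm.
#' @param affine Optional shared 4x4 voxel-to-world matrix.
#' @param subject_ids Optional character ids; defaults to `names(data)`.
#' @return An object of class `gm_volume_set`.
#' @export
gm_volume_set <- function(data, voxel_size_mm, affine = NULL, subject_ids = NULL) {
  stopifnot(is.list(data), length(data) >= 1L)
  subject_ids <- subject_ids %||% names(data)
  if (is.null(subject_ids) || anyDuplicated(subject_ids) || any(!nzchar(subject_ids)))
    stop("subject_ids must be unique non-empty identifiers", call. = FALSE)
  if (length(subject_ids) != length(data))
    stop("subject_ids must align with data", call. = FALSE)
  shape <- dim(data[[1]])
  if (length(shape) != 3L) stop("volumes must be 3D arrays", call. = FALSE)
  for (i in seq_along(data)) {
    if (!identical(dim(data[[i]]), shape))
      stop(sprintf("volume grid mismatch for subject '%s'", subject_ids[i]), call. = FALSE)
  }
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be positive", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size_mm
  }
  names(data) <- subject_ids
  structure(list(data = data, voxel_size_mm = voxel_size_mm, affine = affine,
                 subject_ids = subject_ids),
            class = "gm_volume_set")
}

#' @export
print.gm_volume_set <- function(x, ...) {
  cat(sprintf("gm_volume_set: %d subjects, grid %s, voxel %s mm\n",
              length(x$data), paste(dim(x$data[[1]]), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

#' Read per-subject NIfTI volumes into a common-grid set
#'
#' All files must share grid shape, voxel size and affine; any mismatch is an
#' error naming the offending file rather than a silent resample.
#'
#' @param paths Character vector of NIfTI file paths.
#' @param subject_ids Optional ids; defaults to file basenames without extension.
#' @return A [gm_volume_set()].
#' @export
read_volumes <- function(paths, subject_ids = NULL) {
  stopifnot(length(paths) >= 1L)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("input file not found: %s", paste(missing, collapse = ", ")), call. = FALSE)
  subject_ids <- subject_ids %||% sub("\\.nii(\\.gz)?$", "", basename(paths))
  vols <- lapply(paths, nifti_read)
  ref <- vols[[1]]
  for (i in seq_along(vols)) {
    v <- vols[[i]]
    if (!identical(dim(v$data), dim(ref$data)) ||
        max(abs(v$voxel_size_mm - ref$voxel_size_mm)) > 1e-4 ||
        max(abs(v$affine - ref$affine)) > 1e-3)
      stop(sprintf("grid/affine mismatch in '%s' relative to '%s'",
                   paths[i], paths[1]), call. = FALSE)
  }
  gm_volume_set(lapply(vols, `[[`, "data"), ref$voxel_size_mm, ref$affine,
                subject_ids = subject_ids)
}

#' Write one volume of a set (or a bare array) to NIfTI
#'
#' @param volume A 3D array.
#' @param path Output path.
#' @param voxel_size_mm Voxel size in mm.
#' @param affine Optional 4x4 affine.
#' @param datatype passed to [nifti_write()].
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size_mm, affine = NULL,
                         datatype = "float32") {
  nifti_write(volume, path, voxel_size_mm, affine, datatype)
}

# 1D Gaussian smoothing operator as an n x n matrix. The kernel is the
# normalized discrete Gaussian truncated at 4 sigma. Boundary rules:
#   zero    - mass leaving the grid is lost (zero padding)
#   nearest - out-of-range kernel mass accumulates on the edge voxel
.smooth_operator <- function(n, sigma_vox, boundary = "zero") {
  if (sigma_vox <= 0) return(diag(n))
  L <- max(1L, ceiling(4 * sigma_vox))
  k <- (-L):L
  w <- exp(-k^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (m in seq_along(k)) {
    for (i in seq_len(n)) {
      j <- i + k[m]
      if (j < 1L || j > n) {
        if (boundary == "nearest") {
          j <- min(max(j, 1L), n)
        } else {
          next
        }
      }
      K[i, j] <- K[i, j] + w[m]
    }
  }
  K
}

# separable 3D Gaussian smoothing of one array; sigma given per axis in voxels
.smooth_array <- function(a, sigma_vox, boundary = "zero") {
  d <- dim(a)
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    K <- .smooth_operator(d[ax], sigma_vox[ax], boundary)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    inv <- order(perm)
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- array(K %*% matrix(ap, dp[1], dp[2] * dp[3]), dp)
    a <- aperm(ap, inv)
  }
  a
}

#' Gaussian-smooth every volume in a set
#'
#' Applies isotropic-in-mm Gaussian smoothing with the given full width at
#' half maximum; the per-axis kernel sigma in voxels is
#' `fwhm_mm / (voxel_size_mm * 2*sqrt(2*log(2)))`. `fwhm_mm = 0` is the
#' identity. The default boundary rule is zero padding (mass crossing the grid
#' edge is lost); `"nearest"` replicates edge voxels instead.
#'
#' @param set A [gm_volume_set()].
#' @param fwhm_mm Scalar FWHM in mm, `>= 0`.
#' @param boundary `"zero"` (default) or `"nearest"`.
#' @return A smoothed `gm_volume_set`.
#' @export
smooth_volumes <- function(set, fwhm_mm, boundary = c("zero", "nearest")) {
  stopifnot(inherits(set, "gm_volume_set"))
  boundary <- match.arg(boundary)
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("fwhm_mm must be a single value >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(set)
  sigma_vox <- fwhm_mm / (set$voxel_size_mm * 2 * sqrt(2 * log(2)))
  set$data <- lapply(set$data, .smooth_array, sigma_vox = sigma_vox,
                     boundary = boundary)
  set
}

#' Build the analysis brain mask
#'
#' A voxel enters the mask iff the mean across subjects exceeds the threshold,
#' restricting the features to voxels containing gray matter.
#'
#' @param set A [gm_volume_set()].
#' @param mean_threshold Threshold on the across-subject mean, `>= 0`.
#' @return A `brain_mask`: logical 3D array with attribute `n_voxels_in`.
#' @export
build_mask <- function(set, mean_threshold = 0.1) {
  stopifnot(inherits(set, "gm_volume_set"))
  if (mean_threshold < 0) stop("mean_threshold must be >= 0", call. = FALSE)
  m <- Reduce(`+`, set$data) / length(set$data)
  mask <- m > mean_threshold
  if (!any(mask))
    stop("empty brain mask: lower mean_threshold", call. = FALSE)
  structure(mask, n_voxels_in = sum(mask), class = c("brain_mask", class(mask)))
}

#' Total tissue volume of a map, in ml
#'
#' Sum of voxel values times the voxel volume in mm^3, divided by 1000. On a
#' modulated gray-matter map this is the total GM volume; in the synthetic
#' world (where no other tissue maps exist) it stands in for total
#' intracranial volume.
#'
#' @param x A 3D array or a [gm_volume_set()].
#' @param voxel_size_mm Voxel size (required for bare arrays).
#' @return A single value, or a named vector for a set.
#' @export
compute_tiv <- function(x, voxel_size_mm = NULL) {
  if (inherits(x, "gm_volume_set")) {
    return(vapply(x$data, compute_tiv, numeric(1),
                  voxel_size_mm = x$voxel_size_mm))
  }
  if (is.null(voxel_size_mm)) stop("voxel_size_mm required for a bare array")
  if (any(x < 0)) stop("volume must be nonnegative", call. = FALSE)
  sum(x) * prod(rep_len(voxel_size_mm, 3L)) / 1000
}

#' Vectorize masked voxels into a subjects-by-voxels feature matrix
#'
#' Column j holds the mask's j-th voxel in the mask's linear (column-major)
#' voxel order, so the mapping is stable across calls and invertible via
#' [unvectorize()].
#'
#' @param set A [gm_volume_set()].
#' @param mask A `brain_mask` on the same grid.
#' @return Numeric matrix with `subject_ids` rownames and attribute `mask`.
#' @export
vectorize <- function(set, mask) {
  stopifnot(inherits(set, "gm_volume_set"))
  if (!identical(dim(mask), dim(set$data[[1]])))
    stop("mask grid does not match volume grid", call. = FALSE)
  idx <- which(mask)
  X <- t(vapply(set$data, function(v) v[idx], numeric(length(idx))))
  rownames(X) <- set$subject_ids
  attr(X, "mask") <- mask
  X
}

#' Restore a masked feature vector to a full 3D volume
#'
#' @param values Numeric vector, one value per masked voxel.
#' @param mask The `brain_mask` used for [vectorize()].
#' @param fill Value outside the mask (default 0).
#' @return A 3D array.
#' @export
unvectorize <- function(values, mask, fill = 0) {
  idx <- which(mask)
  if (length(values) != length(idx))
    stop("value length does not match mask voxel count", call. = FALSE)
  out <- array(fill, dim = dim(mask))
  out[idx] <- values
  out
}

#' Residual-forming projection for a covariate design
#'
#' Builds the projection `R = I - X (X'X)^- X'` for a design matrix `X`
#' (intercept included), using the pseudo-inverse when the design is
#' rank-deficient (with a warning). `R` is symmetric, idempotent, and
#' annihilates the design columns.
#'
#' @param design Numeric matrix, n subjects by k columns including intercept.
#' @return A `residualizer` with elements `design`, `coef_op` (the operator
#'   `(X'X)^- X'`), `R`, and `rank`.
#' @export
residualizer <- function(design) {
  design <- as.matrix(design)
  s <- svd(design)
  tol <- max(dim(design)) * .Machine$double.eps * max(s$d, 0)
  r <- sum(s$d > tol)
  if (r < ncol(design))
    warning("rank-deficient covariate design; using pseudo-inverse", call. = FALSE)
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  coef_op <- s$v %*% (dinv * t(s$u))        # (X'X)^- X'
  R <- diag(nrow(design)) - design %*% coef_op
  structure(list(design = design, coef_op = coef_op, R = R, rank = r),
            class = "residualizer")
}

#' Remove covariate effects from feature columns
#'
#' Fits per-column regressions of the features on the covariate design over
#' `fit_rows` and subtracts the fitted values from all rows. With
#' `fit_rows = NULL` the projection is estimated on every row, which is the
#' whole-sample ("paper mode") behaviour; passing the training rows of a
#' cross-validation fold gives the leakage-safe variant.
#'
#' @param features Subjects-by-features numeric matrix.
#' @param covariates Covariate matrix (one row per subject). An intercept
#'   column is appended unless one is already present.
#' @param fit_rows Integer rows used to estimate the projection.
#' @return List with residualized `features` (attributes preserved) and the
#'   fitted `residualizer`.
#' @export
residualize <- function(features, covariates, fit_rows = NULL) {
  X <- .with_intercept(as.matrix(covariates))
  if (nrow(X) != nrow(features))
    stop("covariates must have one row per subject", call. = FALSE)
  fit_rows <- fit_rows %||% seq_len(nrow(features))
  rz <- residualizer(X[fit_rows, , drop = FALSE])
  beta <- rz$coef_op %*% features[fit_rows, , drop = FALSE]
  out <- features - X %*% beta
  attributes(out) <- attributes(features)
  list(features = out, residualizer = rz)
}

# append an intercept unless a constant column is already present
.with_intercept <- function(X) {
  has_const <- ncol(X) > 0 &&
    any(apply(X, 2, function(c) max(c) == min(c) && c[1] != 0))
  if (!has_const) X <- cbind(`(intercept)` = 1, X)
  X
}

#' Build a covariate design from a participant table
#'
#' @param table Participant table with `age_years` and `sex` columns.
#' @param mode `"none"`, `"age_sex"` or `"age_sex_tiv"`.
#' @param tiv Per-subject TIV (ml), required for `"age_sex_tiv"`.
#' @return A covariate matrix without intercept (`NULL` for `"none"`).
#' @export
covariate_design <- function(table, mode = c("none", "age_sex", "age_sex_tiv"),
                             tiv = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(NULL)
  X <- cbind(age = table$age_years, sexM = as.numeric(table$sex == "M"))
  if (mode == "age_sex_tiv") {
    if (is.null(tiv)) stop("tiv required for mode 'age_sex_tiv'", call. = FALSE)
    X <- cbind(X, tiv = as.numeric(tiv))
  }
  X
}
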