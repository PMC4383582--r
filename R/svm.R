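# Linear hard-margin SVM, trained in the dual on the subjects-by-subjects
# Gram matrix (the natural form when voxels vastly outnumber subjects).
#
# "Hard margin" is realized as a soft-margin machine with a very large box
# constraint plus an explicit post-hoc separability check: if any dual
# coefficient sits at the bound while its margin is violated, the data are
# declared non-separable instead of silently absorbing slack.

#' Train a linear hard-margin SVM
#'
#' Solves the C-SVM dual over the Gram matrix by sequential minimal
#' optimization, then reconstructs the primal weight map
#' `w = sum_i alpha_i y_i x_i` and bias `b`. With the default
#' `C_effective = 1e8` and separable data this is the hard-margin machine:
#' every training margin satisfies `y_i f(x_i) >= 1 - kkt_tol` and support
#' vectors sit on the margin.
#'
#' @param features Subjects-by-features numeric matrix (rows = subjects).
#' @param labels Integer labels in `{-1, +1}`, `+1` being the case (preterm)
#'   group; both classes must be present.
#' @param C_effective Box constraint used to realize the hard margin.
#' @param eps SMO duality-gap stopping tolerance.
#' @param kkt_tol Tolerance on the margin KKT conditions.
#' @param allow_violations If `TRUE`, bound-constrained (margin-violating)
#'   solutions are accepted and flagged instead of raising the
#'   "not separable" error; use a moderate `C_effective` in that mode.
#' @param gram Optional precomputed `tcrossprod(features)`.
#' @return A `linear_svm` model: weights `w`, bias `b`, dual coefficients
#'   `alpha`, `sv_indices`, training labels and ids, `C_effective`, and the
#'   training decision values.
#' @export
train_linear_svm <- function(features, labels, C_effective = 1e8,
                             eps = 1e-6, kkt_tol = 1e-4,
                             allow_violations = FALSE, gram = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L)))
    stop("labels must be -1 or +1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  if (length(labels) != nrow(features))
    stop("one label per feature row required", call. = FALSE)
  if (!all(is.finite(features)))
    stop("features must be finite", call. = FALSE)
  ids <- rownames(features) %||% as.character(seq_len(nrow(features)))

  K <- gram %||% tcrossprod(features)
  fit <- .dual_fit(K, labels, C_effective, eps, kkt_tol)
  if (!fit$converged)
    warning("dual solver did not reach the requested tolerance", call. = FALSE)

  alpha <- fit$alpha
  f <- fit$decision
  at_bound <- alpha > C_effective * (1 - 1e-6)
  violated <- labels * f < 1 - kkt_tol
  if (!allow_violations && any(at_bound & violated)) {
    bad <- ids[at_bound & violated]
    stop(sprintf("training data not separable under a hard margin; violating subjects: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sv_tol <- 1e-6 * max(alpha)
  structure(list(
    w = drop(crossprod(features, alpha * labels)),
    b = fit$b,
    alpha = alpha,
    sv_indices = which(alpha > sv_tol),
    labels = labels,
    subject_ids = ids,
    C_effective = C_effective,
    kkt_tol = kkt_tol,
    sv_tol = sv_tol,
    decision_train = f,
    margin_violations = which(at_bound & violated),
    converged = fit$converged,
    n_features = ncol(features)),
    class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("linear_svm: %d training subjects, %d features, %d support vectors\n",
              length(x$labels), x$n_features, length(x$sv_indices)))
  if (length(x$margin_violations))
    cat(sprintf("  soft-margin fit: %d margin violations (C = %g)\n",
                length(x$margin_violations), x$C_effective))
  invisible(x)
}

#' Decision scores (signed distance-to-boundary biomarker)
#'
#' The prediction score of a subject is `f(x) = w . x + b`: the dot product
#' of the image with the weight map plus the bias. Positive scores are
#' preterm-like, negative term-like.
#'
#' @param model A `linear_svm`.
#' @param features Matrix with the model's feature columns (same mask and
#'   column order as at training).
#' @return Named numeric vector of scores.
#' @export
decision_scores <- function(model, features) {
  stopifnot(inherits(model, "linear_svm"))
  features <- as.matrix(features)
  if (ncol(features) != length(model$w))
    stop("feature columns do not match the model's weight vector", call. = FALSE)
  drop(features %*% model$w + model$b)
}

#' Predicted group labels from decision scores
#'
#' Ties at exactly `f = 0` go to the control class (-1), an arbitrary but
#' fixed convention.
#'
#' @param scores Numeric decision scores.
#' @return Integer labels in `{-1, +1}`.
#' @export
predict_labels <- function(scores) {
  ifelse(scores > 0, 1L, -1L)
}

#' Voxel weight map of a trained model
#'
#' Places the weight vector back on the 3D grid (zero outside the mask). The
#' value at a voxel is its signed discriminative weight: positive weights
#' push toward the preterm side.
#'
#' @param model A `linear_svm`.
#' @param mask The `brain_mask` whose [vectorize()] produced the training
#'   features.
#' @return A 3D array, NIfTI-writable via [write_volume()].
#' @export
weight_map <- function(model, mask) {
  stopifnot(inherits(model, "linear_svm"))
  if (sum(mask) != length(model$w))
    stop("mask voxel count does not match the model's weight vector", call. = FALSE)
  unvectorize(model$w, mask)
}
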