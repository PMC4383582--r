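# Label-permutation inference for the global classification statistics and
# for the voxelwise weight map.
#
# Conventions (documented, not inherited from any reference implementation):
#   * p = (1 + #{null >= observed}) / (1 + n_perm), so p is never 0 and the
#     smallest reportable value with N permutations is 1 / (N + 1);
#   * only the labels are permuted -- covariates travel with their subjects,
#     so the question tested is whether group assignment is informative
#     given the images;
#   * the voxel map is two-sided on |w|, since weights carry both signs.

#' Permutation p-value under the add-one convention
#'
#' @param n_as_extreme Number of null draws at least as extreme as observed.
#' @param n_perm Number of permutations.
#' @return `(1 + n_as_extreme) / (1 + n_perm)`.
#' @export
perm_pvalue <- function(n_as_extreme, n_perm) {
  (1 + n_as_extreme) / (1 + n_perm)
}

# n_perm label permutations as rows of subject indices, drawn from one
# seeded stream so runs are reproducible
.draw_permutations <- function(n, n_perm, seed) {
  set.seed(seed)
  t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
}

.cv_statistic <- function(scores, labels, statistic) {
  switch(statistic,
         accuracy = mean(predict_labels(scores) == labels),
         auc = auc_mann_whitney(scores, labels),
         stop(sprintf("unknown statistic '%s'", statistic), call. = FALSE))
}

#' Global permutation test of leave-one-out classification
#'
#' Recomputes the full leave-one-out pipeline (including any fold-wise
#' residualization) on each of `n_perm` uniformly random label permutations
#' and compares the observed accuracy and/or AUC against the null draws.
#'
#' @inheritParams loo_cv
#' @param statistic `"accuracy"`, `"auc"`, or both (both are computed from
#'   the same permutation stream).
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutation stream.
#' @param permutations Optional matrix of permutation index rows, overriding
#'   the seeded draw (for audits and forced cases).
#' @param eps Solver tolerance used for *both* the observed and the permuted
#'   refits inside the test. The default (1e-3) is looser than the training
#'   default: permutation statistics (accuracy, AUC) depend on decision
#'   scores only at a far coarser resolution, and label-permuted hard-margin
#'   problems are the slowest to polish to high precision.
#' @return A `perm_null` for a single statistic, otherwise a named list of
#'   `perm_null` objects.
#' @export
permute_global <- function(features, labels, statistic = c("accuracy", "auc"),
                           n_perm = 999, seed = 1, C_effective = 1e8,
                           covariates = NULL, leakage = c("foldwise", "paper"),
                           shortcut = TRUE, allow_violations = FALSE,
                           permutations = NULL, eps = 1e-3) {
  statistic <- match.arg(statistic, several.ok = TRUE)
  leakage <- match.arg(leakage)
  labels <- .check_two_classes(labels, min_each = 2L)
  if (is.null(permutations)) {
    if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
    permutations <- .draw_permutations(length(labels), n_perm, seed)
  }
  n_perm <- nrow(permutations)

  if (is.null(covariates) || leakage == "paper") {
    # label-free preprocessing: residualize once, reuse the Gram matrix for
    # every draw, and accept (rare) margin violations silently -- under
    # permuted labels the statistic, not the separability certificate, is
    # the object of interest
    Xeff <- if (is.null(covariates)) as.matrix(features) else
      residualize(as.matrix(features), covariates)$features
    K <- tcrossprod(Xeff)
    run_loo <- function(y) .loo_scores(K, y, C_effective, eps,
                                       1e-4, shortcut)$score
  } else {
    run_loo <- function(y) loo_cv(features, y, C_effective = C_effective,
                                  covariates = covariates, leakage = leakage,
                                  shortcut = shortcut, eps = eps,
                                  allow_violations = TRUE)$score
  }
  obs_scores <- run_loo(labels)
  observed <- vapply(statistic, function(s) .cv_statistic(obs_scores, labels, s),
                     numeric(1))
  null <- matrix(NA_real_, n_perm, length(statistic),
                 dimnames = list(NULL, statistic))
  for (b in seq_len(n_perm)) {
    yb <- labels[permutations[b, ]]
    sb <- run_loo(yb)
    null[b, ] <- vapply(statistic, function(s) .cv_statistic(sb, yb, s),
                        numeric(1))
  }
  make_null <- function(s) {
    k <- sum(null[, s] >= observed[[s]])
    structure(list(statistic = s, observed = observed[[s]],
                   null = null[, s], n_perm = n_perm, seed = seed,
                   p_value = perm_pvalue(k, n_perm),
                   p_bound_form = if (k == 0)
                     sprintf("p < 1/%d (no null draw reached the observed value)", n_perm)
                   else sprintf("p = (1+%d)/(1+%d)", k, n_perm)),
              class = "perm_null")
  }
  if (length(statistic) == 1L) make_null(statistic) else
    stats::setNames(lapply(statistic, make_null), statistic)
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("permutation null (%s): observed %.4f, max null %.4f over %d perms, p = %.4g\n",
              x$statistic, x$observed, max(x$null), x$n_perm, x$p_value))
  cat(sprintf("  convention: (1+k)/(1+N); %s\n", x$p_bound_form))
  invisible(x)
}

#' Voxelwise permutation p-value map of the SVM weights
#'
#' Trains the full-sample model, then retrains on `n_perm` label
#' permutations, recording the weight vector each time. The voxel statistic
#' is the *relative* weight magnitude `|w_v| / ||w||` (the weight map
#' normalized to unit length over the mask): a hard-margin weight vector's
#' overall scale is the inverse margin, which explodes under permuted
#' labels, so raw `|w|` comparisons would be confounded by scale while the
#' relative weight asks where the discriminative load sits. The per-voxel
#' two-sided p-value is
#' `(1 + #{|w_perm|/||w_perm|| >= |w_obs|/||w_obs||}) / (1 + n_perm)`,
#' uncorrected for multiple comparisons.
#'
#' @inheritParams permute_global
#' @param mask Optional `brain_mask`; when supplied the p map and observed
#'   weight map are also returned as 3D volumes (p = 1 outside the mask).
#' @return A `pvalue_map`: per-voxel `p`, `n_perm`, `sidedness`, observed
#'   weights, and optional volumes.
#' @export
weight_pvalue_map <- function(features, labels, n_perm = 199, seed = 1,
                              C_effective = 1e8, mask = NULL,
                              permutations = NULL, eps = 1e-3) {
  features <- as.matrix(features)
  labels <- .check_two_classes(labels, min_each = 2L)
  if (is.null(permutations)) {
    if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
    permutations <- .draw_permutations(length(labels), n_perm, seed)
  }
  n_perm <- nrow(permutations)
  K <- tcrossprod(features)              # label-free: reused across draws
  model <- train_linear_svm(features, labels, C_effective, eps = eps, gram = K)
  w_obs <- model$w
  rel_obs <- abs(w_obs) / sqrt(sum(w_obs^2))
  count <- integer(length(w_obs))
  for (b in seq_len(n_perm)) {
    yb <- labels[permutations[b, ]]
    fit <- .dual_fit(K, yb, C_effective, eps)
    wb <- drop(crossprod(features, fit$alpha * yb))
    count <- count + (abs(wb) / sqrt(sum(wb^2)) >= rel_obs)
  }
  p <- perm_pvalue(count, n_perm)
  out <- list(p = p, n_perm = n_perm, sidedness = "two-sided", seed = seed,
              w_observed = w_obs)
  if (!is.null(mask)) {
    out$p_volume <- unvectorize(p, mask, fill = 1)
    out$w_volume <- unvectorize(w_obs, mask)
  }
  structure(out, class = "pvalue_map")
}

#' @export
print.pvalue_map <- function(x, ...) {
  cat(sprintf("pvalue_map: %d voxels, %d permutations, %s on |w|; min p = %.4g\n",
              length(x$p), x$n_perm, x$sidedness, min(x$p)))
  invisible(x)
}
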