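# Cross-validation schemes, confusion-matrix metrics, ROC/AUC and the
# DeLong test for correlated ROC curves.

.check_two_classes <- function(labels, min_each = 1L) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be -1 or +1", call. = FALSE)
  if (sum(labels == 1L) < min_each || sum(labels == -1L) < min_each)
    stop("both classes must be present", call. = FALSE)
  labels
}

.cv_result <- function(ids, fold, labels, scores, scheme) {
  out <- data.frame(id = ids, fold = fold, label = as.integer(labels),
                    score = as.numeric(scores),
                    predicted = predict_labels(scores),
                    stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Leave-one-out cross-validation of the linear SVM
#'
#' Each subject is scored by a model trained on all other subjects. Three
#' residualization modes are supported: none, `"paper"` (covariates removed
#' once on the whole sample before the loop, as a whole-sample analysis
#' would), and `"foldwise"` (the residual-forming projection refit on each
#' fold's training rows, which is the leakage-safe default when covariates
#' are given).
#'
#' When no fold-dependent residualization is in play, the hard-margin
#' shortcut is available: a held-out subject that is not a support vector of
#' the full-sample model (and lies strictly outside the margin) inherits the
#' full-model score, because removing a non-support point leaves the
#' hard-margin solution unchanged. `shortcut = FALSE` forces the naive
#' retrain-per-fold loop; the two agree to numerical tolerance.
#'
#' @param features Subjects-by-features matrix.
#' @param labels Labels in `{-1, +1}`; at least two per class.
#' @param C_effective Box constraint (default hard-margin surrogate `1e8`).
#' @param covariates Optional covariate matrix (no intercept needed).
#' @param leakage `"foldwise"` or `"paper"`; only used with covariates.
#' @param shortcut Use the non-support-vector shortcut where valid.
#' @param allow_violations Accept margin-violating (soft) fits, e.g. for a
#'   single-feature TIV classifier.
#' @param eps,kkt_tol Solver tolerances, see [train_linear_svm()].
#' @return A `cv_result` data frame (id, fold, label, score, predicted) with
#'   a `scheme` attribute.
#' @export
loo_cv <- function(features, labels, C_effective = 1e8, covariates = NULL,
                   leakage = c("foldwise", "paper"), shortcut = TRUE,
                   allow_violations = FALSE, eps = 1e-6, kkt_tol = 1e-4) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 4L) stop("leave-one-out needs at least 4 subjects", call. = FALSE)
  labels <- .check_two_classes(labels, min_each = 2L)
  leakage <- match.arg(leakage)
  ids <- rownames(features) %||% as.character(seq_len(n))

  covariate_mode <- if (is.null(covariates)) "none" else leakage
  if (covariate_mode == "paper") {
    features <- residualize(features, covariates)$features
  }

  if (covariate_mode %in% c("none", "paper")) {
    K <- tcrossprod(features)
    res <- .loo_scores(K, labels, C_effective, eps, kkt_tol, shortcut)
    if (!res$converged)
      warning("dual solver did not reach the requested tolerance in some folds",
              call. = FALSE)
    if (!allow_violations) {
      # separability is checked on the full sample (from the LOO solver's own
      # full-model fit); LOO folds of a separable sample remain separable
      f_full <- drop(K %*% (res$alpha_full * labels)) + res$b_full
      bad <- res$alpha_full > C_effective * (1 - 1e-6) &
        labels * f_full < 1 - kkt_tol
      if (any(bad))
        stop(sprintf("training data not separable under a hard margin; violating subjects: %s",
                     paste(ids[bad], collapse = ", ")), call. = FALSE)
    }
    scores <- res$score
    refit <- res$refit
  } else {
    scores <- numeric(n)
    refit <- rep(TRUE, n)
    for (i in seq_len(n)) {
      Xr <- residualize(features, covariates, fit_rows = setdiff(seq_len(n), i))$features
      m <- train_linear_svm(Xr[-i, , drop = FALSE], labels[-i], C_effective,
                            eps, kkt_tol, allow_violations = allow_violations)
      scores[i] <- decision_scores(m, Xr[i, , drop = FALSE])
    }
  }
  out <- .cv_result(ids, seq_len(n), labels, scores,
                    scheme = list(type = "loo", covariate_mode = covariate_mode,
                                  shortcut = shortcut,
                                  C_effective = C_effective,
                                  allow_violations = allow_violations))
  attr(out, "refit") <- refit
  out
}

#' Split-half validation: train on a random half, classify the rest
#'
#' Samples the requested number of training subjects per group without
#' replacement (reproducibly from `seed`), trains once, and scores every
#' held-out subject.
#'
#' @inheritParams loo_cv
#' @param n_train_case,n_train_control Training subjects drawn per group.
#' @param seed RNG seed for the split.
#' @return A `cv_result` over the held-out subjects.
#' @export
split_half_validation <- function(features, labels, n_train_case,
                                  n_train_control, seed, C_effective = 1e8,
                                  covariates = NULL,
                                  leakage = c("foldwise", "paper"),
                                  allow_violations = FALSE,
                                  eps = 1e-6, kkt_tol = 1e-4) {
  features <- as.matrix(features)
  labels <- .check_two_classes(labels)
  leakage <- match.arg(leakage)
  ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  cases <- which(labels == 1L); controls <- which(labels == -1L)
  if (n_train_case > length(cases) || n_train_control > length(controls))
    stop("requested training counts exceed group sizes", call. = FALSE)
  set.seed(seed)
  train <- c(sample(cases, n_train_case), sample(controls, n_train_control))
  test <- setdiff(seq_along(labels), train)
  if (!length(test)) stop("empty test set: training counts equal group sizes",
                          call. = FALSE)
  if (length(unique(labels[train])) < 2L)
    stop("both classes required in the training half", call. = FALSE)
  Xr <- features
  if (!is.null(covariates))
    Xr <- residualize(features, covariates,
                      fit_rows = if (leakage == "foldwise") train else NULL)$features
  m <- train_linear_svm(Xr[train, , drop = FALSE], labels[train], C_effective,
                        eps, kkt_tol, allow_violations = allow_violations)
  scores <- decision_scores(m, Xr[test, , drop = FALSE])
  out <- .cv_result(ids[test], rep("holdout", length(test)), labels[test], scores,
                    scheme = list(type = "split_half", seed = seed,
                                  n_train_case = n_train_case,
                                  n_train_control = n_train_control,
                                  covariate_mode = if (is.null(covariates)) "none" else leakage))
  attr(out, "train_ids") <- ids[train]
  out
}

#' Confusion-matrix summaries of a cross-validation result
#'
#' The positive class is `+1` (preterm): sensitivity is the fraction of true
#' cases predicted positive, specificity the fraction of true controls
#' predicted negative. A metric whose denominator class is empty is reported
#' as `NA` and listed in `undefined`, never silently zero.
#'
#' @param predicted A `cv_result`, or an integer vector of predicted labels.
#' @param labels True labels (ignored when `predicted` is a `cv_result`).
#' @return A `confusion_metrics` list: `tp`, `fn`, `tn`, `fp`, `accuracy`,
#'   `sensitivity`, `specificity`, `undefined`.
#' @export
confusion_metrics <- function(predicted, labels = NULL) {
  if (inherits(predicted, "cv_result")) {
    labels <- predicted$label
    predicted <- predicted$predicted
  }
  if (is.null(labels)) stop("labels required", call. = FALSE)
  stopifnot(length(predicted) == length(labels))
  tp <- sum(labels == 1L & predicted == 1L)
  fn <- sum(labels == 1L & predicted == -1L)
  tn <- sum(labels == -1L & predicted == -1L)
  fp <- sum(labels == -1L & predicted == 1L)
  undefined <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { undefined <- c(undefined, "specificity"); NA_real_ }
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 accuracy = (tp + tn) / length(labels),
                 sensitivity = sens, specificity = spec,
                 undefined = undefined),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | sensitivity %s | specificity %s (TP %d FN %d TN %d FP %d)\n",
              x$accuracy, format(x$sensitivity, digits = 4),
              format(x$specificity, digits = 4), x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' AUC by the Mann-Whitney pairwise statistic
#'
#' `AUC = (#{pos > neg} + 0.5 #{ties}) / (n_pos * n_neg)`, computed through
#' midranks. Equals the trapezoidal area under [roc_curve()].
#'
#' @param scores Numeric scores, larger = more case-like.
#' @param labels Labels in `{-1, +1}`.
#' @return The AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- .check_two_classes(labels)
  pos <- labels == 1L
  m <- sum(pos); n <- sum(!pos)
  r <- rank(scores)                     # midranks handle ties
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

#' ROC curve by threshold sweep
#'
#' Sweeps thresholds over the unique scores in descending order (tied scores
#' form a single threshold) and returns the (FPR, TPR) path from (0,0) to
#' (1,1) together with its trapezoidal area.
#'
#' @inheritParams auc_mann_whitney
#' @return A `roc_curve`: list with `points` (threshold, fpr, tpr) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- .check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  tp <- cumsum(y == 1L)[keep]
  fp <- cumsum(y == -1L)[keep]
  pts <- data.frame(threshold = c(Inf, s[keep]),
                    fpr = c(0, fp / sum(labels == -1L)),
                    tpr = c(0, tp / sum(labels == 1L)))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

# DeLong structural components of one score vector:
# V10_i = mean_j psi(s_pos_i, s_neg_j), V01_j = mean_i psi(s_pos_i, s_neg_j)
.delong_components <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  psi <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors measured on the same subjects,
#' using the structural components to estimate the covariance of the paired
#' AUC estimates: `S = S10 / n_pos + S01 / n_neg`, `z = dAUC / sqrt(var)`,
#' two-sided normal p. Per-AUC Wald confidence intervals (truncated to
#' `[0, 1]`) are included. A zero variance of the difference (e.g. identical
#' scores) is flagged as degenerate with `p = 1` rather than dividing by
#' zero.
#'
#' @param scores_a,scores_b Two score vectors over the same subjects.
#' @param labels Labels in `{-1, +1}`.
#' @param ci_level Confidence level for the per-AUC intervals.
#' @return A `delong_result` list.
#' @export
delong_compare <- function(scores_a, scores_b, labels, ci_level = 0.95) {
  labels <- .check_two_classes(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pos <- labels == 1L
  m <- sum(pos); n <- sum(!pos)
  ca <- .delong_components(scores_a, pos)
  cb <- .delong_components(scores_b, pos)
  S10 <- cov(cbind(ca$v10, cb$v10))
  S01 <- cov(cbind(ca$v01, cb$v01))
  S <- S10 / m + S01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  degenerate <- !is.finite(var_diff) || var_diff <= .Machine$double.eps
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- (ca$auc - cb$auc) / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  q <- qnorm(1 - (1 - ci_level) / 2)
  ci <- function(auc, v) pmin(pmax(auc + c(-1, 1) * q * sqrt(max(v, 0)), 0), 1)
  structure(list(auc_a = ca$auc, auc_b = cb$auc,
                 var_diff = max(var_diff, 0), z = z, p_value = p,
                 degenerate = degenerate, ci_level = ci_level,
                 ci_a = ci(ca$auc, S[1, 1]), ci_b = ci(cb$auc, S[2, 2])),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong: AUC_a = %.4f [%.4f, %.4f], AUC_b = %.4f [%.4f, %.4f]\n",
              x$auc_a, x$ci_a[1], x$ci_a[2], x$auc_b, x$ci_b[1], x$ci_b[2]))
  if (x$degenerate) {
    cat("  degenerate variance of the AUC difference; p = 1\n")
  } else {
    cat(sprintf("  z = %.3f, two-sided p = %.3g\n", x$z, x$p_value))
  }
  invisible(x)
}
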