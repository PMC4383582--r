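test_that("leave-one-out separates well-separated clusters perfectly", {
  set.seed(1)
  X <- rbind(matrix(rnorm(10 * 2, mean = 3), 10, 2),
             matrix(rnorm(10 * 2, mean = -3), 10, 2))
  y <- rep(c(1L, -1L), each = 10)
  cv <- loo_cv(X, y)
  expect_s3_class(cv, "cv_result")
  expect_equal(nrow(cv), 20L)
  expect_equal(sort(cv$fold), 1:20)     # every subject scored exactly once
  expect_equal(confusion_metrics(cv)$accuracy, 1.0)
})

test_that("the non-support-vector shortcut reproduces the naive LOO loop", {
  for (s in 1:4) {
    co <- generate_cohort(small_cohort_config(n_case = 8, n_control = 8, seed = 20 + s))
    fx <- cohort_features(co)
    fast <- loo_cv(fx$X, fx$y, shortcut = TRUE)
    naive <- loo_cv(fx$X, fx$y, shortcut = FALSE)
    expect_identical(fast$predicted, naive$predicted)
    expect_equal(fast$score, naive$score, tolerance = 1e-6)
    expect_true(all(attr(naive, "refit")))   # naive refits every fold
  }
})

test_that("LOO guards its preconditions", {
  X <- matrix(rnorm(6), 3, 2)
  expect_error(loo_cv(X, c(1L, -1L, 1L)), "at least 4")
  X <- matrix(rnorm(10), 5, 2)
  expect_error(loo_cv(X, c(1L, 1L, 1L, 1L, -1L)), "both classes")
})

test_that("foldwise and whole-sample residualization both run and differ in kind", {
  co <- generate_cohort(small_cohort_config(seed = 31))
  fx <- cohort_features(co)
  Z <- covariate_design(co$table, "age_sex")
  cv_fold <- loo_cv(fx$X, fx$y, covariates = Z, leakage = "foldwise")
  cv_paper <- loo_cv(fx$X, fx$y, covariates = Z, leakage = "paper")
  expect_equal(attr(cv_fold, "scheme")$covariate_mode, "foldwise")
  expect_equal(attr(cv_paper, "scheme")$covariate_mode, "paper")
  expect_equal(nrow(cv_fold), nrow(fx$X))
  # same subjects, slightly different scores (projection fit differs per fold)
  expect_gt(cor(cv_fold$score, cv_paper$score), 0.9)
})

test_that("split-half validation scores every held-out subject once", {
  co <- generate_cohort(small_cohort_config(n_case = 10, n_control = 9, seed = 5))
  fx <- cohort_features(co)
  sh <- split_half_validation(fx$X, fx$y, 5, 4, seed = 99)
  expect_equal(nrow(sh), 19 - 9)
  expect_false(any(sh$id %in% attr(sh, "train_ids")))
  sh2 <- split_half_validation(fx$X, fx$y, 5, 4, seed = 99)
  expect_identical(sh$id, sh2$id)
  expect_identical(sh$score, sh2$score)
  sh3 <- split_half_validation(fx$X, fx$y, 5, 4, seed = 100)
  expect_false(identical(sort(sh$id), sort(sh3$id)))
  expect_error(split_half_validation(fx$X, fx$y, 11, 4, seed = 1),
               "exceed group sizes")
  expect_error(split_half_validation(fx$X, fx$y, 10, 9, seed = 1),
               "empty test set")
})

test_that("confusion metrics use +1 = preterm as the positive class", {
  pred <- c(rep(1L, 67), rep(-1L, 7), rep(-1L, 65), rep(1L, 4))
  truth <- c(rep(1L, 74), rep(-1L, 69))
  m <- confusion_metrics(pred, truth)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(67, 7, 65, 4))
  expect_equal(m$sensitivity, 67 / 74, tolerance = 1e-12)
  expect_equal(m$specificity, 65 / 69, tolerance = 1e-12)
  expect_equal(m$accuracy, 132 / 143, tolerance = 1e-12)

  all_neg <- confusion_metrics(rep(-1L, 10), rep(c(1L, -1L), 5))
  expect_equal(all_neg$sensitivity, 0)
  expect_equal(all_neg$specificity, 1)
  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  # empty class flagged, not silently zero
  onesided <- confusion_metrics(rep(1L, 3), rep(1L, 3))
  expect_true(is.na(onesided$specificity))
  expect_true("specificity" %in% onesided$undefined)
})

test_that("AUC equals the Mann-Whitney pairwise count", {
  expect_equal(auc_mann_whitney(1:4, c(-1, -1, 1, 1)), 1.0)
  expect_equal(auc_mann_whitney(1:4, c(1, -1, 1, -1)), 0.25) # 1 of 4 pairs
  expect_equal(auc_mann_whitney(rep(2, 6), rep(c(1, -1), 3)), 0.5)

  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == -1]
    acc <- 0
    for (a in pos) for (b in neg) acc <- acc + (a > b) + 0.5 * (a == b)
    acc / (length(pos) * length(neg))
  }
  set.seed(10)
  for (r in 1:25) {
    n <- sample(6:25, 1)
    y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
    s <- sample(seq_len(8), n, replace = TRUE)  # heavy ties
    expect_equal(auc_mann_whitney(s, y), brute(s, y), tolerance = 1e-10)
  }
})

test_that("ROC curves are monotone paths whose area equals the pairwise AUC", {
  s <- c(5, 4, 3, 2); y <- c(1, 1, -1, -1)
  r <- roc_curve(s, y)
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_true(any(r$points$fpr == 0 & r$points$tpr == 1))  # passes (0,1)
  expect_equal(r$auc, 1)
  r0 <- roc_curve(-s, y)   # anti-separating
  expect_true(any(r0$points$fpr == 1 & r0$points$tpr == 0))
  expect_equal(r0$auc, 0)

  set.seed(11)
  for (i in 1:30) {
    n <- sample(8:40, 1)
    y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
    s <- round(rnorm(n), 1)
    r <- roc_curve(s, y)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(utils::tail(r$points$fpr, 1), 1)
    expect_equal(utils::tail(r$points$tpr, 1), 1)
    expect_equal(r$auc, auc_mann_whitney(s, y), tolerance = 1e-10)
  }
})

test_that("DeLong structural components match a hand evaluation", {
  y <- c(1, 1, -1, -1)
  sa <- c(0.9, 0.8, 0.2, 0.1)
  sb <- c(0.9, 0.1, 0.8, 0.2)
  res <- delong_compare(sa, sb, y)
  expect_equal(res$auc_a, 1.0)
  # pairs for B: 0.9>0.8, 0.9>0.2, 0.1<0.8, 0.1<0.2 -> 2 of 4
  expect_equal(res$auc_b, 0.5)
  # hand evaluation: psi matrices over the 2x2 positive-negative pairs
  # A: psi = [[1,1],[1,1]]       -> V10 = (1,1),   V01 = (1,1)
  # B: psi = [[1,1],[0,0]]       -> V10 = (1,0),   V01 = (0.5,0.5)
  # S10 = cov((1,1),(1,0)) = [[0,0],[0,0.5]], S01 = 0
  # var(diff) = (0 + 0.5 - 2*0)/2 + 0 = 0.25
  expect_equal(res$var_diff, 0.25)
  expect_equal(res$z, (1 - 0.5) / 0.5)
  expect_equal(res$p_value, 2 * pnorm(-1))

  # swapping the scores negates z and preserves p
  swap <- delong_compare(sb, sa, y)
  expect_equal(swap$z, -res$z)
  expect_equal(swap$p_value, res$p_value)

  # identical scores: degenerate variance, p = 1, no division by zero
  dg <- delong_compare(sa, sa, y)
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
})

test_that("the reported AUC confidence interval brackets the point estimate", {
  set.seed(12)
  y <- rep(c(1, -1), each = 40)
  s <- rnorm(80) + 0.8 * (y == 1)
  res <- delong_compare(s, rnorm(80), y, ci_level = 0.95)
  expect_true(res$ci_a[1] <= res$auc_a && res$auc_a <= res$ci_a[2])
  expect_true(all(res$ci_a >= 0 & res$ci_a <= 1))
})

test_that("AUC is invariant to strictly increasing score transforms", {
  set.seed(13)
  y <- sample(c(-1, 1), 30, replace = TRUE); y[1:2] <- c(-1, 1)
  s <- rnorm(30)
  expect_equal(auc_mann_whitney(exp(s), y), auc_mann_whitney(s, y))
  expect_equal(auc_mann_whitney(rank(s), y), auc_mann_whitney(s, y))
})
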