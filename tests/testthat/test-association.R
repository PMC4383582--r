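test_that("Pearson correlation: exact cases and the direct-formula oracle", {
  expect_equal(pearson_corr(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_corr(1:3, c(6, 4, 2))$r, -1)
  expect_error(pearson_corr(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_corr(1:2, 1:2), "3 complete pairs")

  set.seed(1)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  res <- pearson_corr(x, y)
  # rank-free direct covariance/variance formula
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)    # independent p-value route
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_equal(res$n, 50L)

  # symmetry and positive-affine invariance
  expect_equal(pearson_corr(x, y)$r, pearson_corr(y, x)$r)
  expect_equal(pearson_corr(2 * x + 5, y)$r, res$r, tolerance = 1e-12)

  # pairwise missing handling
  y[3] <- NA
  expect_equal(pearson_corr(x, y)$n, 49L)
})

test_that("correlate_scores handles subsets and surfaces undefined rows", {
  co <- generate_cohort(cohort_config(seed = 14))
  fx <- cohort_features(co)
  cv <- loo_cv(fx$X, fx$y)
  tab <- correlate_scores(co$table, cv$score, c("ga_weeks", "bw_g"), "cases")
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$n <= sum(co$table$group == 1)))
  expect_error(correlate_scores(co$table, cv$score, "bw_g", "everyone"))

  flat <- correlate_scores(co$table, rep(1, nrow(co$table)), "bw_g", "cases")
  expect_true(is.na(flat$r))
  expect_match(flat$note, "zero variance")
})

test_that("partial correlation equals the regress-both-then-correlate oracle", {
  set.seed(2)
  n <- 60
  Z <- cbind(rnorm(n), rnorm(n))
  x <- 0.5 * Z[, 1] + rnorm(n)
  y <- -0.3 * Z[, 1] + 0.2 * x + rnorm(n)
  res <- partial_corr(x, y, Z)
  rx <- stats::residuals(stats::lm(x ~ Z))
  ry <- stats::residuals(stats::lm(y ~ Z))
  expect_equal(res$r, cor(rx, ry), tolerance = 1e-10)
  expect_equal(res$df, n - 2 - 2)
  tt <- res$r * sqrt(res$df / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(tt), res$df), tolerance = 1e-12)

  expect_equal(partial_corr(x, y, NULL)$r, pearson_corr(x, y)$r)
  # covariate identical to the variable: zero residual variance
  expect_error(partial_corr(x, x, matrix(x)), "zero residual variance")
})

test_that("partial correlation with empty covariates reduces to plain Pearson", {
  set.seed(3)
  x <- rnorm(30); y <- rnorm(30)
  a <- partial_corr(x, y, NULL)
  b <- pearson_corr(x, y)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("WHO stratification uses the printed half-open boundaries", {
  expect_equal(as.character(who_stratify(27.9, 1)), "extremely_preterm")
  expect_equal(as.character(who_stratify(28.0, 1)), "very_preterm")
  expect_equal(as.character(who_stratify(31.99, 1)), "very_preterm")
  expect_equal(as.character(who_stratify(32.0, 1)), "moderately_preterm")
  expect_equal(as.character(who_stratify(36.0, 1)), "moderately_preterm")
  expect_equal(as.character(who_stratify(40, -1)), "term")
  expect_equal(who_code(who_stratify(c(27, 29, 33, 40), c(1, 1, 1, -1))),
               c(3, 2, 1, -1))
  expect_error(who_stratify(37.5, 1), "GA >= 37")
  expect_error(who_stratify(NA_real_, 1), "finite")
})

test_that("WHO categories partition every case exactly once", {
  co <- generate_cohort(cohort_config(seed = 15))
  cat <- who_stratify(co$table$ga_weeks, co$table$group)
  counts <- table(cat)
  expect_equal(sum(counts[c("moderately_preterm", "very_preterm",
                            "extremely_preterm")]),
               sum(co$table$group == 1))
  expect_equal(unname(counts["term"]), sum(co$table$group == -1),
               ignore_attr = TRUE)
})

test_that("subgroup mean scores are plain per-category means", {
  sub <- factor(c("moderately_preterm", "very_preterm", "very_preterm"),
                levels = levels(who_stratify(30, 1)))
  out <- subgroup_mean_scores(c(0.2, 1.0, 2.0), sub)
  expect_equal(nrow(out), 2L)   # empty categories absent, not zero
  expect_equal(out$mean_score[out$category == "very_preterm"], 1.5)
  expect_equal(out$n[out$category == "moderately_preterm"], 1L)
  same <- subgroup_mean_scores(rep(3, 3), sub)
  expect_true(all(same$mean_score == 3))
})

test_that("pairwise subgroup classification restricts, relabels and errors", {
  co <- generate_cohort(small_cohort_config(n_case = 14, n_control = 10, seed = 16))
  fx <- cohort_features(co)
  cv <- pairwise_subgroup_classification(fx$X, co$table, "controls", "+3")
  cat <- who_stratify(co$table$ga_weeks, co$table$group)
  expect_equal(nrow(cv), sum(cat %in% c("term", "extremely_preterm")))
  expect_error(pairwise_subgroup_classification(fx$X, co$table, "+2", "+2"),
               "overlap")
  expect_error(pairwise_subgroup_classification(fx$X, co$table, "controls", "+9"),
               "unknown subgroup")
})

test_that("SGA-excluded analysis drops only flagged cases", {
  co <- generate_cohort(cohort_config(seed = 17))
  fx <- cohort_features(co)
  cv <- sga_excluded_analysis(fx$X, co$table)
  n_sga <- sum(co$table$group == 1 & co$table$sga)
  expect_equal(attr(cv, "n_excluded"), n_sga)
  expect_equal(nrow(cv), nrow(co$table) - n_sga)
  expect_equal(sum(cv$label == 1), 74 - n_sga)   # 58 non-SGA cases
  expect_equal(sum(cv$label == -1), 69)

  # with sga_fraction = 0 the analysis equals the full LOO run
  co0 <- generate_cohort(small_cohort_config(seed = 18))
  co0$table$sga[] <- FALSE
  fx0 <- cohort_features(co0)
  full <- loo_cv(fx0$X, fx0$y)
  excl <- sga_excluded_analysis(fx0$X, co0$table)
  expect_equal(excl$score, full$score, tolerance = 1e-12)

  co0$table$sga[co0$table$group == 1] <- TRUE
  expect_error(sga_excluded_analysis(fx0$X, co0$table), "no non-SGA")
})

test_that("TIV-only classification runs soft-margin on the single feature", {
  set.seed(19)
  y <- rep(c(1L, -1L), each = 15)
  tiv_sep <- c(rnorm(15, 1100, 5), rnorm(15, 1300, 5))   # fully separated
  res <- tiv_only_classification(tiv_sep, y)    # smaller TIV = case
  expect_equal(confusion_metrics(res$cv)$accuracy, 1.0)
  expect_true(res$soft_margin)
  expect_error(tiv_only_classification(rep(5, 30), y), "constant")

  # group-independent TIV carries no real signal: never systematically above
  # chance. (Below chance is expected here: with w ~ 0 the decision follows
  # the bias term, which under leave-one-out tracks the training-fold
  # majority -- the opposite of the held-out class. This anti-learning bias
  # of LOO with majority-driven classifiers on balanced null data is a known
  # artifact, so "accuracy ~ 0.5" is only an upper-side statement.)
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    tiv <- rnorm(30, 1200, 60)
    confusion_metrics(tiv_only_classification(tiv, y)$cv)$accuracy
  }, numeric(1))
  expect_lt(mean(accs), 0.5 + 2 * sd(accs) / sqrt(length(accs)))
})
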