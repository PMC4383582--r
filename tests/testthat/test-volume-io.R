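test_that("read_volumes enforces a common grid and names offenders", {
  dir <- tempfile("vols"); dir.create(dir)
  set.seed(3)
  p1 <- file.path(dir, "a.nii"); p2 <- file.path(dir, "b.nii")
  nifti_write(array(runif(4^3), c(4, 4, 4)), p1, 1.5)
  nifti_write(array(runif(4^3), c(4, 4, 4)), p2, 1.5)
  set <- read_volumes(c(p1, p2))
  expect_s3_class(set, "gm_volume_set")
  expect_identical(set$subject_ids, c("a", "b"))

  p3 <- file.path(dir, "c.nii")
  nifti_write(array(runif(5^3), c(5, 5, 5)), p3, 1.5)
  expect_error(read_volumes(c(p1, p3)), "c\\.nii")
  expect_error(read_volumes(file.path(dir, "missing.nii")), "not found")
  unlink(dir, recursive = TRUE)
})

test_that("smoothing: identity at fwhm 0, delta peak matches the discrete kernel", {
  set.seed(4)
  vols <- list(s1 = array(runif(12^3), c(12, 12, 12)))
  set <- gm_volume_set(vols, c(1.5, 1.5, 1.5))
  expect_identical(smooth_volumes(set, 0)$data$s1, vols$s1)

  delta <- array(0, c(15, 15, 15)); delta[8, 8, 8] <- 1
  dset <- gm_volume_set(list(d = delta), c(1.5, 1.5, 1.5))
  sm <- smooth_volumes(dset, 6)$data$d
  # oracle: central weight of the normalized discrete separable kernel
  sigma <- 6 / (1.5 * 2 * sqrt(2 * log(2)))
  k <- seq(-ceiling(4 * sigma), ceiling(4 * sigma))
  w <- exp(-k^2 / (2 * sigma^2)); w <- w / sum(w)
  expect_equal(max(sm), max(w)^3, tolerance = 1e-10)
  expect_equal(which(sm == max(sm)), which(delta == 1))
  # continuous Gaussian peak agrees with the discrete central weight to ~2%
  expect_equal(max(sm), (1 / (sqrt(2 * pi) * sigma))^3, tolerance = 0.02)
  # interior support: total sum preserved under zero padding
  expect_equal(sum(sm), 1, tolerance = 1e-6)
})

test_that("smoothing is linear and respects the boundary rule", {
  set.seed(5)
  u <- array(runif(10^3), c(10, 10, 10)); v <- array(runif(10^3), c(10, 10, 10))
  mk <- function(a) gm_volume_set(list(x = a), c(2, 2, 2))
  s <- function(a, boundary = "zero") smooth_volumes(mk(a), 4, boundary)$data$x
  expect_equal(s(3 * u + v), 3 * s(u) + s(v), tolerance = 1e-8)
  cst <- array(1, c(10, 10, 10))
  expect_equal(s(cst, "nearest"), cst, tolerance = 1e-12)  # replication keeps constants
  sz <- s(cst, "zero")
  expect_lt(max(sz), 1 + 1e-12)   # zero padding loses mass at the edges
  expect_equal(sz[5, 5, 5], 1, tolerance = 1e-9)  # kernel support fits: unaffected
})

test_that("mask construction thresholds the across-subject mean", {
  a <- array(0, c(3, 3, 3)); b <- array(0, c(3, 3, 3))
  a[1, 1, 1] <- 0.4; b[1, 1, 1] <- 0.4   # mean 0.4
  a[2, 2, 2] <- 0.3; b[2, 2, 2] <- 0.1   # mean 0.2
  set <- gm_volume_set(list(a = a, b = b), 1)
  m <- build_mask(set, 0.25)
  expect_equal(sum(m), 1L)
  expect_true(m[1, 1, 1])
  expect_equal(sum(build_mask(set, 0)), 2L)
  expect_error(build_mask(set, 10), "lower mean_threshold")
  full <- gm_volume_set(list(x = array(1, c(3, 3, 3))), 1)
  expect_equal(sum(build_mask(full, 0)), 27L)
})

test_that("TIV is the voxel sum times voxel volume in ml", {
  ones <- array(1, c(10, 10, 10))
  expect_equal(compute_tiv(ones, c(1, 1, 1)), 1.0)
  expect_equal(compute_tiv(array(0, c(4, 4, 4)), c(2, 2, 2)), 0)
  set.seed(6)
  v <- array(runif(6^3), c(6, 6, 6))
  # brute-force loop oracle
  acc <- 0
  for (i in 1:6) for (j in 1:6) for (k in 1:6) acc <- acc + v[i, j, k]
  expect_equal(compute_tiv(v, c(1.5, 1.5, 2)), acc * 1.5 * 1.5 * 2 / 1000,
               tolerance = 1e-9)
  expect_error(compute_tiv(array(-1, c(2, 2, 2)), 1), "nonnegative")
})

test_that("vectorize/unvectorize is a stable invertible mapping on the mask", {
  set.seed(7)
  co <- generate_cohort(small_cohort_config(n_case = 3, n_control = 3, seed = 3))
  mask <- build_mask(co$volumes, 0.1)
  X <- vectorize(co$volumes, mask)
  expect_identical(dim(X), c(6L, as.integer(sum(mask))))
  expect_identical(rownames(X), co$volumes$subject_ids)
  v1 <- unvectorize(X[1, ], mask)
  expect_equal(v1[mask], co$volumes$data[[1]][mask])
  expect_true(all(v1[!mask] == 0))
  # column order stable across calls
  expect_identical(X, vectorize(co$volumes, mask))

  # tiny hand-built case
  a <- array(0, c(2, 2, 1)); a[1, 1, 1] <- 5; a[2, 2, 1] <- 7
  m <- array(FALSE, c(2, 2, 1)); m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE
  X2 <- vectorize(gm_volume_set(list(s = a), 1), m)
  expect_equal(as.numeric(X2), c(5, 7))  # column-major mask order
  wrong <- array(TRUE, c(3, 3, 1))
  expect_error(vectorize(gm_volume_set(list(s = a), 1), wrong), "mask")
})

test_that("residual-forming projection: examples, oracle and invariants", {
  # intercept-only design centers a column
  out <- residualize(matrix(c(1, 2, 3), 3, 1), matrix(0, 3, 0))
  expect_equal(drop(out$features), c(-1, 0, 1))

  set.seed(8)
  n <- 30; k <- 3; p <- 8
  Z <- matrix(rnorm(n * k), n, k)
  Fm <- matrix(rnorm(n * p), n, p)
  res <- residualize(Fm, Z)
  # column-wise least-squares-then-subtract oracle
  oracle <- vapply(seq_len(p), function(j)
    stats::residuals(stats::lm(Fm[, j] ~ Z)), numeric(n))
  expect_equal(unclass(res$features), oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
  # idempotence
  twice <- residualize(res$features, Z)$features
  expect_equal(unclass(twice), unclass(res$features), tolerance = 1e-10)
  # orthogonality to the design
  X <- cbind(1, Z)
  expect_lt(max(abs(crossprod(X, res$features))), 1e-6)

  # projection matrix invariants over random designs
  for (s in 1:5) {
    set.seed(s)
    n <- sample(20:200, 1); k <- sample(1:5, 1)
    rz <- residualizer(cbind(1, matrix(rnorm(n * k), n, k)))
    expect_lt(max(abs(rz$R - t(rz$R))), 1e-8)
    expect_lt(max(abs(rz$R %*% rz$R - rz$R)), 1e-8)
    expect_lt(max(abs(rz$R %*% rz$design)), 1e-8)
  }
  # rank deficiency falls back to the pseudo-inverse with a warning
  Zdup <- cbind(Z, Z[, 1])
  expect_warning(residualize(Fm, Zdup), "rank-deficient")
})

test_that("fold-wise residualization fits the projection on training rows only", {
  set.seed(9)
  n <- 20
  Z <- matrix(rnorm(n), n, 1)
  Fm <- matrix(2 * Z[, 1] + rnorm(n, 0, 0.1), n, 1)
  fit_rows <- 1:15
  out <- residualize(Fm, Z, fit_rows = fit_rows)
  beta <- stats::coef(stats::lm(Fm[fit_rows, 1] ~ Z[fit_rows, 1]))
  expect_equal(drop(out$features), drop(Fm - cbind(1, Z) %*% beta),
               tolerance = 1e-10)
})

test_that("TIV tracks the generator's true global scale factor", {
  co <- generate_cohort(cohort_config(seed = 21))
  tiv <- compute_tiv(co$volumes)
  expect_gt(cor(tiv, co$truth$scale), 0.9)
})
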