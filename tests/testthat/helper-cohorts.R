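# Shared fixtures: everything is generated in code at test time.

# small, fast cohort with a strong effect on a coarse grid
small_cohort_config <- function(n_case = 12, n_control = 12, seed = 1,
                                effect_scale = 1, tiv_group_gap = 0.05,
                                grid = c(10L, 10L, 10L)) {
  regions <- list(
    list(center = c(5.5, 7.5, 5.5), radius = 1.6, sign = +1, amplitude = 0.12),
    list(center = c(5.5, 3.5, 5.5), radius = 1.6, sign = -1, amplitude = 0.12))
  cohort_config(n_case = n_case, n_control = n_control, grid_shape = grid,
                effect_regions = regions, effect_scale = effect_scale,
                tiv_group_gap = tiv_group_gap, seed = seed)
}

# features + labels straight from a cohort (no pipeline smoothing, to keep
# unit tests fast; the generator's own smoothing already correlates voxels)
cohort_features <- function(cohort, threshold = 0.1) {
  mask <- build_mask(cohort$volumes, threshold)
  list(X = vectorize(cohort$volumes, mask), y = cohort$table$group,
       mask = mask)
}

# random linearly separable instance with a guaranteed margin
random_separable <- function(n, p, seed, margin = 1.5) {
  set.seed(seed)
  y <- sample(c(-1L, 1L), n, replace = TRUE)
  y[1:2] <- c(-1L, 1L)
  u <- rnorm(p); u <- u / sqrt(sum(u^2))
  X <- matrix(rnorm(n * p), n, p) + margin * outer(y, u)
  list(X = X, y = y)
}

# hard-margin primal solved by quadprog: min ||w||^2 s.t. y(w.x + b) >= 1.
# Independent oracle route (primal, active-set QP) for the dual SMO solver.
qp_hard_margin <- function(X, y, ridge = 1e-9) {
  p <- ncol(X)
  D <- diag(c(rep(1, p), ridge))
  A <- t(cbind(X * y, y))
  sol <- quadprog::solve.QP(D, rep(0, p + 1), A, rep(1, nrow(X)))$solution
  list(w = sol[1:p], b = sol[p + 1])
}
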