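# Dual-solver dispatch.
#
# The C++ SMO solver (second-order working-set selection) is fast on
# well-conditioned problems but can grind on nearly-degenerate hard-margin
# fits, e.g. label-permuted cohorts of heavily smoothed maps where the
# separating margin is minuscule. Every fit therefore runs SMO under an
# iteration budget and, on non-convergence, falls back to an exact
# NNLS-style active-set solve of the same dual:
#
#   min 1/2 a'Qa - 1'a,  Q = (yy') .* K,  y'a = 0,  0 <= a <= C,
#
# worked in beta = a*y coordinates, where the stationarity conditions on the
# free set F read K_FF beta_F + b = y_F (given the bound set U at C). Each
# outer step solves that saddle system by dense linear algebra, interpolates
# back to the feasible box if a bound is crossed (Lawson-Hanson style), and
# otherwise admits the worst KKT violator. Exact solves make the fallback
# insensitive to the conditioning that stalls SMO.

.SMO_BUDGET <- 2e5

# Active-set solve over the subjects with exclude-mask support (used for
# leave-one-out without copying Gram submatrices). Returns beta, alpha, b,
# decision values f over all rows, and a convergence flag.
.active_set_fit <- function(K, y, C, kkt_tol = 1e-6, exclude = integer(0),
                            init = NULL, max_outer = NULL) {
  n <- length(y)
  max_outer <- max_outer %||% (30L * n + 200L)
  ridge <- 1e-10 * (mean(diag(K)) + 1)

  state <- integer(n)                  # 0 zero, 1 free, 2 at C, -1 excluded
  beta <- numeric(n)
  state[exclude] <- -1L
  if (!is.null(init)) {
    state[init$free] <- 1L
    state[init$upper] <- 2L
    beta <- init$beta
    beta[exclude] <- 0
  } else {
    inc <- setdiff(seq_len(n), exclude)
    state[c(inc[y[inc] == 1][1], inc[y[inc] == -1][1])] <- 1L
  }

  solve_sub <- function(Fidx, Uidx) {
    m <- length(Fidx)
    bu <- C * y[Uidx]
    r <- y[Fidx] - if (length(Uidx))
      drop(K[Fidx, Uidx, drop = FALSE] %*% bu) else 0
    A <- rbind(cbind(K[Fidx, Fidx, drop = FALSE] + diag(ridge, m), 1),
               c(rep(1, m), 0))
    rhs <- c(r, -sum(bu))
    sol <- tryCatch(solve(A, rhs), error = function(e) {
      sv <- svd(A)
      dinv <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
      drop(sv$v %*% (dinv * crossprod(sv$u, rhs)))
    })
    list(beta = sol[seq_len(m)], b = sol[m + 1])
  }

  converged <- FALSE
  b <- 0
  for (it in seq_len(max_outer)) {
    Fidx <- which(state == 1L)
    if (!length(Fidx)) {               # re-seed with one point per class
      inc <- which(state == 0L)
      seed <- c(inc[y[inc] == 1][1], inc[y[inc] == -1][1])
      seed <- seed[!is.na(seed)]
      if (!length(seed)) break
      state[seed] <- 1L
      Fidx <- which(state == 1L)
    }
    Uidx <- which(state == 2L)
    sub <- solve_sub(Fidx, Uidx)
    beta_new <- numeric(n)
    beta_new[Uidx] <- C * y[Uidx]
    beta_new[Fidx] <- sub$beta
    alpha_new <- beta_new * y
    alpha_cur <- beta * y

    # bound tolerance scales with the solution, never with the (huge) C
    a_tol <- 1e-9 * max(1, max(abs(alpha_new[Fidx])))
    lo <- Fidx[alpha_new[Fidx] < -a_tol]
    hi <- Fidx[alpha_new[Fidx] > C + a_tol]
    if (length(lo) || length(hi)) {
      # walk toward the candidate until the first bound blocks
      tau <- 1
      block <- NA_integer_; to_state <- 0L
      for (i in lo) {
        ti <- alpha_cur[i] / (alpha_cur[i] - alpha_new[i])
        if (ti < tau) { tau <- ti; block <- i; to_state <- 0L }
      }
      for (i in hi) {
        ti <- (C - alpha_cur[i]) / (alpha_new[i] - alpha_cur[i])
        if (ti < tau) { tau <- ti; block <- i; to_state <- 2L }
      }
      beta <- beta + tau * (beta_new - beta)
      if (!is.na(block)) {
        state[block] <- to_state
        beta[block] <- if (to_state == 2L) C * y[block] else 0
      }
      next
    }

    beta <- beta_new
    b <- sub$b
    act <- which(beta != 0)
    f <- drop(K[, act, drop = FALSE] %*% beta[act]) + b
    viol <- rep(0, n)
    zset <- state == 0L
    viol[zset] <- pmax(0, 1 - kkt_tol - y[zset] * f[zset])
    uset <- state == 2L
    viol[uset] <- pmax(0, y[uset] * f[uset] - 1 - kkt_tol)
    if (max(viol) == 0) { converged <- TRUE; break }
    worst <- which.max(viol)
    state[worst] <- 1L
  }

  if (!exists("f", inherits = FALSE)) {
    act <- which(beta != 0)
    f <- drop(K[, act, drop = FALSE] %*% beta[act]) + b
  }
  list(alpha = beta * y, beta = beta, b = b, decision = f,
       free = which(state == 1L), upper = which(state == 2L),
       converged = converged, iterations = it)
}

# single dual fit: SMO within budget, exact active-set on non-convergence
.dual_fit <- function(K, y, C, eps = 1e-6, kkt_tol = 1e-4) {
  fit <- .smo_solve(K, y, C, eps, max_iter = .SMO_BUDGET)
  if (fit$converged) {
    fit$solver <- "smo"
    return(fit)
  }
  act <- .active_set_fit(K, y, C, kkt_tol = min(kkt_tol, 1e-6))
  list(alpha = act$alpha, b = act$b, decision = act$decision,
       converged = act$converged, iterations = act$iterations,
       solver = "active_set")
}

# LOO scores via the active-set solver, each fold warm-started from the
# full-sample solution with the held-out subject removed and the equality
# constraint repaired on its class
.loo_scores_active <- function(K, y, C, kkt_tol = 1e-4, shortcut = TRUE) {
  n <- length(y)
  tol <- min(kkt_tol, 1e-6)
  full <- .active_set_fit(K, y, C, kkt_tol = tol)
  amax <- max(full$alpha)
  sv_tol <- 1e-6 * amax
  scores <- numeric(n)
  refit <- logical(n)
  converged <- full$converged
  for (i in seq_len(n)) {
    if (shortcut && full$alpha[i] <= sv_tol &&
        y[i] * full$decision[i] > 1 + kkt_tol) {
      scores[i] <- full$decision[i]
      next
    }
    init <- list(free = setdiff(full$free, i),
                 upper = setdiff(full$upper, i),
                 beta = full$beta)
    init$beta[i] <- 0
    # repair sum(beta) = 0 by shifting the removed mass onto a free
    # same-class subject (hard margin: the upper bound is far away)
    if (full$beta[i] != 0) {
      host <- init$free[y[init$free] == y[i]]
      if (length(host)) {
        host <- host[which.max(init$beta[host] * y[i])]
        moved <- init$beta[host] + full$beta[i]
        if (abs(moved) < 0.99 * C) init$beta[host] <- moved else init <- NULL
      } else {
        init <- NULL
      }
    }
    fit <- .active_set_fit(K, y, C, kkt_tol = tol, exclude = i, init = init)
    converged <- converged && fit$converged
    scores[i] <- fit$decision[i]
    refit[i] <- TRUE
  }
  list(score = scores, refit = refit, alpha_full = full$alpha,
       b_full = full$b, converged = converged)
}

# LOO scores with automatic solver fallback
.loo_scores <- function(K, y, C, eps = 1e-6, kkt_tol = 1e-4, shortcut = TRUE) {
  res <- .loo_scores_gram(K, y, C, eps, kkt_tol, shortcut,
                          max_iter = .SMO_BUDGET)
  if (res$converged) return(res)
  .loo_scores_active(K, y, C, kkt_tol, shortcut)
}
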