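# Independent oracles used across the suite.

# Exact C-SVM dual solution for tiny problems by active-set enumeration:
# every variable is assigned to {0, C, free}; the free block is solved from
# the KKT stationarity system with the equality constraint, feasibility is
# checked, and the best feasible objective wins. Exhaustive, so exact up to
# linear-algebra precision for n <= ~8.
qp_oracle <- function(K, y, C) {
  n <- length(y)
  Q <- (y %o% y) * K
  obj <- function(a) sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
  best <- list(objective = -Inf, alpha = NULL)
  states <- expand.grid(rep(list(0:2), n))
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    a <- ifelse(st == 1L, C, 0)
    free <- which(st == 2L)
    if (length(free)) {
      bound <- which(st != 2L)
      A <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                 c(y[free], 0))
      rhs1 <- rep(1, length(free))
      if (length(bound))
        rhs1 <- rhs1 - drop(Q[free, bound, drop = FALSE] %*% a[bound])
      rhs <- c(rhs1, -sum(y[bound] * a[bound]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      af <- sol[seq_along(free)]
      if (any(af < -1e-9) || any(af > C + 1e-9)) next
      a[free] <- pmin(pmax(af, 0), C)
    }
    if (abs(sum(a * y)) > 1e-8) next
    o <- obj(a)
    if (o > best$objective) best <- list(objective = o, alpha = a)
  }
  best
}

# decision function from a dual solution on a precomputed kernel
oracle_decision <- function(K_test_train, alpha, y, K_train, C) {
  f0 <- drop(K_train %*% (alpha * y))
  free <- which(alpha > 1e-7 & alpha < C - 1e-7)
  b <- if (length(free)) mean(y[free] - f0[free]) else {
    up <- (y > 0 & alpha < C - 1e-9) | (y < 0 & alpha > 1e-9)
    lo <- (y > 0 & alpha > 1e-9) | (y < 0 & alpha < C - 1e-9)
    (max((y - f0)[up]) + min((y - f0)[lo])) / 2
  }
  drop(K_test_train %*% (alpha * y)) + b
}

rbf_K <- function(X, Z = X, gamma) {
  d <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  exp(-gamma * pmax(d, 0))
}

# a synthetic spec in the clearly separable regime (many strong markers,
# complete table) used by the strong-signal tests
strong_spec <- function(seed, effect_size = 3, n_informative = 24L) {
  synthetic_spec(n_per_class = 10, n_informative = n_informative,
                 effect_size = effect_size, missing_prob = 0, seed = seed)
}
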