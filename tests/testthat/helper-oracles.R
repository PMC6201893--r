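# Independent brute-force oracles used to verify the implementation.
# Deliberately written as naive loops / enumerations, sharing no code with
# the package internals.

# Max-rule estimator by explicit per-visit, per-grid-point counting.
oracle_estimate_max <- function(x, g, grid_pts) {
  t <- length(x)
  rs <- numeric(length(grid_pts))
  for (j in seq_along(grid_pts)) {
    agree <- 0L
    for (k in seq_len(t)) {
      pos <- x[k] >= grid_pts[j]
      if ((pos && g[k] == 1) || (!pos && g[k] == 0)) agree <- agree + 1L
    }
    rs[j] <- agree / t
  }
  best <- max(rs)
  ties <- grid_pts[abs(rs - best) < 1e-12]
  list(q = best, a = stats::median(ties), r = rs)
}

# One-sided (location > 0) signed-rank p-value by enumeration of all
# 2^n sign assignments of the observed (mid)ranks.
oracle_signed_rank_greater <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- drop(signs %*% r)
  mean(ws >= w_obs - 1e-9)
}

# Clopper-Pearson interval by numeric root-finding on binomial tail sums.
oracle_cp_ci <- function(s, n, level = 0.95) {
  alpha <- (1 - level) / 2
  low <- if (s == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(s - 1, n, p, lower.tail = FALSE) - alpha,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  high <- if (s == n) 1 else
    stats::uniroot(function(p) stats::pbinom(s, n, p) - alpha,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(low, high)
}
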