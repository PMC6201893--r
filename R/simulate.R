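#' Configuration of a correlated paired-data simulation
#'
#' Describes the data-generating process used to study the estimator's
#' operating characteristics. The objective outcomes of one subject's `t`
#' visits are multivariate normal: the mean vector cycles a 5-element block
#' (default `(0, 0.5, 1, 1.5, 2)`, the variances cycle
#' `(1, 1.3, 1.6, 1.9, 2.2)`), and every off-diagonal covariance is
#' `rho * sigma_l * sigma_s` for a single correlation `rho` (an
#' exchangeable-correlation structure on heterogeneous variances). Given
#' `x_k`, the dichotomized PRO is Bernoulli: positive with probability
#' `q_true` when `x_k >= a_true`, and negative with probability `q_true`
#' otherwise — so `q_true` is the revealing-truth probability on both sides
#' of the latent threshold `a_true`.
#'
#' @param rho cross-visit correlation in (-1, 1).
#' @param a_true true latent threshold, units of the objective outcome.
#' @param q_true true revealing-truth probability in \[0, 1\].
#' @param t number of visits per subject (positive integer).
#' @param mu_block,var_block 5-element building blocks cycled to length `t`.
#' @param grid the pre-specified [threshold_grid()]; default
#'   `threshold_grid_range(-2, 5, 0.1)` (m = 71), wide enough to bracket the
#'   default thresholds by about two standard deviations.
#' @param n_reps number of Monte-Carlo replicates (default 10000).
#' @param seed optional integer seed; [run_study()] seeds the R stream with
#'   it so identical configurations reproduce bit-identical results.
#' @return Object of class `"sim_config"` with the cycled `mu` and `vars`
#'   vectors attached. Positive definiteness of the implied covariance is
#'   verified at construction.
#' @examples
#' cfg <- sim_config(rho = 0.8, a_true = 1.2, q_true = 0.9, t = 10,
#'                   n_reps = 100, seed = 1)
#' @export
sim_config <- function(rho, a_true, q_true, t,
                       mu_block = c(0, 0.5, 1, 1.5, 2),
                       var_block = c(1, 1.3, 1.6, 1.9, 2.2),
                       grid = threshold_grid_range(-2, 5, 0.1),
                       n_reps = 10000L, seed = NULL) {
  stopifnot(length(rho) == 1L, is.finite(rho), rho > -1, rho < 1,
            length(a_true) == 1L, is.finite(a_true),
            length(q_true) == 1L, is.finite(q_true),
            q_true >= 0, q_true <= 1,
            length(t) == 1L, is.finite(t), t >= 1, t == round(t),
            length(mu_block) >= 1L, all(is.finite(mu_block)),
            length(var_block) >= 1L, all(is.finite(var_block)),
            all(var_block > 0),
            inherits(grid, "threshold_grid"),
            length(n_reps) == 1L, n_reps >= 1, n_reps == round(n_reps))
  cfg <- structure(
    list(rho = rho, a_true = a_true, q_true = q_true, t = as.integer(t),
         mu_block = mu_block, var_block = var_block,
         mu = rep_len(mu_block, t), vars = rep_len(var_block, t),
         grid = grid, n_reps = as.integer(n_reps),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
  build_covariance(cfg)  # fails here if the structure is not PD
  cfg
}

#' Covariance matrix implied by a simulation configuration
#'
#' Diagonal entries are the cycled variances; off-diagonal entry (l, s) is
#' `rho * sigma_l * sigma_s`. Positive definiteness is verified by Cholesky
#' factorization.
#'
#' @param config a [sim_config()].
#' @return A symmetric positive-definite `t x t` matrix.
#' @examples
#' cfg <- sim_config(rho = 0.5, a_true = 0, q_true = 0.8, t = 2, n_reps = 10)
#' build_covariance(cfg)  # off-diagonal 0.5 * sqrt(1.3)
#' @export
build_covariance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sds <- sqrt(config$vars)
  S <- config$rho * (sds %o% sds)
  diag(S) <- config$vars
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop(sprintf("covariance matrix is not positive definite (rho = %g, t = %d)",
                 config$rho, config$t))
  S
}

#' Draw one subject's paired series from a simulation configuration
#'
#' The objective outcomes are one multivariate-normal draw; each PRO
#' response is then Bernoulli conditional on which side of the true latent
#' threshold the outcome fell (success probability `q_true` for a positive
#' response above the threshold and for a negative response below it).
#'
#' @param config a [sim_config()].
#' @param subject_id label for the drawn subject (default `"sim"`).
#' @return A [paired_series()]. Uses the current R random stream; seed it
#'   with `set.seed()` (or use [run_study()], which seeds from the config).
#' @export
draw_subject <- function(config, subject_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  xg <- draw_subjects_matrix(config, 1L)
  paired_series(subject_id, x = xg$x[1, ], g = xg$g[1, ],
                scale_label = sprintf("simulated (a = %g, Q = %g)",
                                      config$a_true, config$q_true))
}

# Vectorized draws: n subjects/replicates at once.
# Returns list(x = n x t matrix, g = n x t 0/1 matrix).
draw_subjects_matrix <- function(config, n) {
  S <- build_covariance(config)
  x <- MASS::mvrnorm(n, mu = config$mu, Sigma = S)
  if (n == 1L) x <- matrix(x, nrow = 1L)
  p <- ifelse(x >= config$a_true, config$q_true, 1 - config$q_true)
  g <- matrix(stats::rbinom(length(p), 1L, as.vector(p)), nrow = n)
  list(x = x, g = g)
}

# Agreement successes (tp + tn) at every grid point for every row of (x, g).
# Returns an n x m integer matrix.
scan_successes_matrix <- function(x, g, grid_points) {
  n <- nrow(x)
  m <- length(grid_points)
  S <- matrix(0L, n, m)
  g1 <- g == 1L
  for (j in seq_len(m))
    S[, j] <- as.integer(rowSums((x >= grid_points[j]) == g1))
  S
}

#' Monte-Carlo study of the estimator's operating characteristics
#'
#' Repeatedly draws a subject from the configuration, estimates Q over the
#' configured grid under the requested rule, and forms the exact binomial
#' confidence interval per replicate; reports the mean estimate, the mean
#' estimated threshold, the coverage of the interval at `q_true`, and the
#' Monte-Carlo standard error of the mean estimate.
#'
#' @param config a [sim_config()]; its `seed` (if any) seeds the R stream.
#' @param rule `"max"` (default) or `"median"`; see [estimate_q()].
#' @param level confidence level for the per-replicate exact interval
#'   (default 0.95).
#' @param compute_a also compute the per-replicate threshold estimate
#'   (default `TRUE`; the tie-median step is the slow part of large runs).
#' @return Object of class `"sim_study_result"`: `config`, `rule`,
#'   `mean_q_hat`, `mean_a_hat`, `coverage`, `mc_se`
#'   (`sd(q_hats)/sqrt(n_reps)`), plus the per-replicate vectors `q_hats`,
#'   `a_hats`, `covered`.
#' @examples
#' cfg <- sim_config(rho = 0.8, a_true = 1.2, q_true = 0.9, t = 10,
#'                   n_reps = 200, seed = 42)
#' run_study(cfg)
#' @export
run_study <- function(config, rule = c("max", "median"), level = 0.95,
                      compute_a = TRUE) {
  rule <- match.arg(rule)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_reps
  t <- config$t
  a_pts <- config$grid$points
  xg <- draw_subjects_matrix(config, n)
  S <- scan_successes_matrix(xg$x, xg$g, a_pts)
  m <- ncol(S)
  if (rule == "max") {
    smax <- S[, 1]
    if (m > 1L) for (j in 2:m) smax <- pmax(smax, S[, j])
    q_hats <- smax / t
    succ <- smax
  } else {
    med_s <- apply(S, 1L, stats::median)  # can end in .5 for even m
    q_hats <- med_s / t
    succ <- as.integer(floor(q_hats * t + 0.5))
  }
  a_hats <- rep(NA_real_, n)
  if (compute_a) {
    if (rule == "max") {
      for (i in seq_len(n))
        a_hats[i] <- stats::median(a_pts[S[i, ] == succ[i]])
    } else {
      for (i in seq_len(n)) {
        d <- abs(S[i, ] - med_s[i])
        a_hats[i] <- stats::median(a_pts[d <= min(d) + 1e-12])
      }
    }
  }
  ci <- vapply(0:t, function(s) exact_binom_ci(s, t, level), numeric(2))
  covered <- ci[1, succ + 1L] <= config$q_true &
    config$q_true <= ci[2, succ + 1L]
  structure(
    list(config = config, rule = rule, level = level,
         mean_q_hat = mean(q_hats),
         mean_a_hat = mean(a_hats),
         coverage = mean(covered),
         mc_se = stats::sd(q_hats) / sqrt(n),
         q_hats = q_hats, a_hats = a_hats, covered = covered,
         n_reps = n),
    class = "sim_study_result"
  )
}

#' @export
print.sim_study_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Monte-Carlo study (%s rule): %d replicates, t = %d, rho = %g, a = %g, Q = %g\n",
              x$rule, x$n_reps, cfg$t, cfg$rho, cfg$a_true, cfg$q_true))
  cat(sprintf("  mean Q-hat = %.4f (MC SE %.4f), mean a-hat = %.4f\n",
              x$mean_q_hat, x$mc_se, x$mean_a_hat))
  cat(sprintf("  coverage of the %.0f%% exact CI at Q = %g: %.4f\n",
              100 * x$level, cfg$q_true, x$coverage))
  invisible(x)
}

#' Convergence of the mean estimate with the number of visits
#'
#' Runs the Monte-Carlo study over a lattice of visit counts and true Q
#' values at fixed correlation and threshold, producing the long-format
#' table behind the convergence figures: the mean max-rule estimate
#' approaches the true Q as `t` grows for every Q > 0.5, while the Q = 0.5
#' column shows the selection bias of the maximum.
#'
#' @param rho,a_true fixed correlation and true threshold.
#' @param q_true_values true Q values (default `c(0.5, 0.6, 0.7, 0.8, 0.9)`).
#' @param t_values visit counts (default `c(5, 10, 20, 40)`).
#' @param n_reps replicates per cell.
#' @param rule estimator rule passed to [run_study()].
#' @param grid threshold grid.
#' @param seed optional master seed; per-cell seeds are derived from it.
#' @return A data.frame (class `"convergence_table"`) with columns `t`,
#'   `q_true`, `mean_q_hat`, `mc_se`, `coverage`, `mean_a_hat`.
#' @seealso [plot_convergence()]
#' @export
convergence_table <- function(rho, a_true,
                              q_true_values = c(0.5, 0.6, 0.7, 0.8, 0.9),
                              t_values = c(5, 10, 20, 40),
                              n_reps = 10000L, rule = "max",
                              grid = threshold_grid_range(-2, 5, 0.1),
                              seed = NULL) {
  cells <- expand.grid(t = t_values, q_true = q_true_values,
                       KEEP.OUT.ATTRS = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- sim_config(rho = rho, a_true = a_true,
                      q_true = cells$q_true[i], t = cells$t[i],
                      grid = grid, n_reps = n_reps, seed = cell_seeds[i])
    res <- run_study(cfg, rule = rule, compute_a = TRUE)
    data.frame(t = cells$t[i], q_true = cells$q_true[i],
               mean_q_hat = res$mean_q_hat, mc_se = res$mc_se,
               coverage = res$coverage, mean_a_hat = res$mean_a_hat)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("convergence_table", "data.frame")
  out
}

#' Plot the convergence of the mean estimate with visit count
#'
#' One line per true Q value, mean estimate against the number of visits,
#' with dashed horizontal references at the true values.
#'
#' @param tbl a [convergence_table()] result.
#' @param ... passed to [graphics::matplot()].
#' @return `tbl`, invisibly.
#' @export
plot_convergence <- function(tbl, ...) {
  stopifnot(inherits(tbl, "convergence_table"))
  qs <- sort(unique(tbl$q_true))
  ts <- sort(unique(tbl$t))
  mat <- sapply(qs, function(q)
    tbl$mean_q_hat[tbl$q_true == q][order(tbl$t[tbl$q_true == q])])
  graphics::matplot(ts, mat, type = "b", pch = 19, lty = 1,
                    xlab = "number of visits t", ylab = "mean Q estimate",
                    ylim = range(c(mat, qs)), ...)
  graphics::abline(h = qs, lty = 3, col = "grey50")
  graphics::legend("topright", legend = sprintf("Q = %g", qs),
                   col = seq_along(qs), lty = 1, pch = 19, bty = "n")
  invisible(tbl)
}

#' Write a synthetic multi-subject fixture to CSV
#'
#' Draws `n_subjects` independent subjects from one configuration and
#' writes them in the long format read by [read_paired_csv()]
#' (`subject_id, visit, x, g`), plus an optional truth sidecar recording
#' the generating `a_true` and `q_true` per subject.
#'
#' @param config a [sim_config()]; its `seed` (if any) seeds the draw.
#' @param n_subjects number of subjects.
#' @param path output CSV path.
#' @param truth_path optional path for the truth sidecar CSV.
#' @return The written data.frame, invisibly.
#' @export
write_fixture <- function(config, n_subjects, path, truth_path = NULL) {
  stopifnot(inherits(config, "sim_config"),
            n_subjects >= 1, n_subjects == round(n_subjects))
  if (!is.null(config$seed)) set.seed(config$seed)
  xg <- draw_subjects_matrix(config, as.integer(n_subjects))
  t <- config$t
  df <- data.frame(
    subject_id = rep(sprintf("S%03d", seq_len(n_subjects)), each = t),
    visit = rep(seq_len(t), times = n_subjects),
    x = as.vector(t(xg$x)),
    g = as.integer(as.vector(t(xg$g)))
  )
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(truth_path))
    utils::write.csv(
      data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)),
                 a_true = config$a_true, q_true = config$q_true),
      truth_path, row.names = FALSE)
  invisible(df)
}
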