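#' Population summary of per-subject Q estimates
#'
#' Confirms the population revealing-truth probability at one
#' dichotomization by the mean of the subject-level estimates with a
#' t-interval on n - 1 degrees of freedom. A PROM is judged able to reveal
#' disease status for the majority of the target population when the lower
#' confidence bound exceeds a pre-specified minimum acceptable probability
#' `delta` (pure chance is 0.5; a stricter delta demands a higher-quality
#' instrument).
#'
#' @param estimates list of [estimate_q()] results, all from the same
#'   dichotomization; at least two (after any eligibility filtering).
#' @param level confidence level (default 0.95).
#' @param delta minimum acceptable revealing-truth probability
#'   (default 0.5, pure chance).
#' @param filter_eligible drop subjects whose PRO never reaches the
#'   dichotomized value or whose objective outcomes are all identical
#'   (default `TRUE`).
#' @return Object of class `"population_q_summary"`: `n_subjects`,
#'   `n_filtered`, `mean_q`, `ci_low`, `ci_high`, `level`, `delta`,
#'   `passes` (`ci_low > delta`) and `scale_label`. The t-interval is not
#'   clipped to \[0, 1\].
#' @examples
#' s1 <- paired_series("A", c(1, 2, 3, 4), c(0, 0, 1, 1))
#' s2 <- paired_series("B", c(1, 2, 3, 4), c(0, 1, 1, 1))
#' g <- threshold_grid(c(1.5, 2.5, 3.5))
#' ests <- lapply(list(s1, s2), function(s) estimate_q(threshold_scan(s, g)))
#' aggregate_q(ests, delta = 0.5)
#' @export
aggregate_q <- function(estimates, level = 0.95, delta = 0.5,
                        filter_eligible = TRUE) {
  stopifnot(is.list(estimates),
            all(vapply(estimates, inherits, logical(1), "q_estimate")))
  if (length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must lie strictly between 0 and 1")
  labels <- unique(vapply(estimates, function(e)
    if (is.null(e$scale_label)) NA_character_ else e$scale_label,
    character(1)))
  labels <- labels[!is.na(labels)]
  if (length(labels) > 1L)
    stop(sprintf("estimates mix dichotomizations: %s",
                 paste(labels, collapse = ", ")))
  n_in <- length(estimates)
  if (filter_eligible)
    estimates <- Filter(function(e) isTRUE(e$eligible), estimates)
  n <- length(estimates)
  if (n < 2L)
    stop(sprintf(paste0("population inference needs at least 2 eligible ",
                        "subjects (got %d of %d read)"), n, n_in))
  q <- vapply(estimates, `[[`, numeric(1), "q_hat")
  mean_q <- mean(q)
  se <- stats::sd(q) / sqrt(n)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * se
  ci <- c(mean_q - half, mean_q + half)
  structure(
    list(n_subjects = n,
         n_filtered = n_in - n,
         mean_q = mean_q,
         ci_low = ci[1],
         ci_high = ci[2],
         level = level,
         delta = delta,
         passes = ci[1] > delta,
         scale_label = if (length(labels)) labels else NULL),
    class = "population_q_summary"
  )
}

#' @export
print.population_q_summary <- function(x, ...) {
  cat(sprintf("Population revealing-truth probability%s\n",
              if (is.null(x$scale_label)) "" else paste0(" at ", x$scale_label)))
  cat(sprintf("  n = %d subjects (%d filtered as ineligible)\n",
              x$n_subjects, x$n_filtered))
  cat(sprintf("  mean Q-hat = %.4f  (%.1f%% CI %.4f-%.4f)\n",
              x$mean_q, 100 * x$level, x$ci_low, x$ci_high))
  cat(sprintf("  lower bound %s delta = %g: PROM %s able to reveal disease status\n",
              if (x$passes) ">" else "<=", x$delta,
              if (x$passes) "judged" else "NOT judged"))
  invisible(x)
}

#' Responsiveness: shift of the latent threshold across dichotomizations
#'
#' When the PRO is dichotomized at a stricter cutoff (z) instead of a looser
#' one (z'), the subject-specific latent threshold on the objective endpoint
#' is expected to rise. The per-subject differences `a_hat(z) - a_hat(z')`
#' quantify the PROM's ability to detect a change in the objective endpoint;
#' because their distribution is typically skewed, the reference statistic
#' is the median and the test is a one-sided Wilcoxon signed-rank test of a
#' positive location shift.
#'
#' @param est_strict list of [estimate_q()] results at the stricter cutoff z.
#' @param est_loose list of [estimate_q()] results at the looser cutoff z',
#'   covering the same subjects.
#' @return Object of class `"threshold_change_summary"`: `n_subjects`,
#'   `n_excluded` (pairs dropped for a missing threshold estimate), `diffs`
#'   (named per-subject differences), `mean_diff`, `median_diff`,
#'   `p_value` (one-sided, location > 0) and `test_name`.
#' @seealso [signed_rank_test()]
#' @export
threshold_change <- function(est_strict, est_loose) {
  stopifnot(is.list(est_strict), is.list(est_loose),
            all(vapply(est_strict, inherits, logical(1), "q_estimate")),
            all(vapply(est_loose, inherits, logical(1), "q_estimate")))
  ids_s <- vapply(est_strict, `[[`, character(1), "subject_id")
  ids_l <- vapply(est_loose, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids_s) || anyDuplicated(ids_l))
    stop("duplicate subject ids within one cutoff's estimates")
  only_s <- setdiff(ids_s, ids_l)
  only_l <- setdiff(ids_l, ids_s)
  if (length(only_s) || length(only_l))
    stop(sprintf("subjects are not paired across cutoffs: %s",
                 paste(c(sprintf("'%s' only at the stricter cutoff", only_s),
                         sprintf("'%s' only at the looser cutoff", only_l)),
                       collapse = "; ")))
  a_s <- vapply(est_strict, `[[`, numeric(1), "a_hat")[order(ids_s)]
  a_l <- vapply(est_loose, `[[`, numeric(1), "a_hat")[order(ids_l)]
  ids <- sort(ids_s)
  ok <- is.finite(a_s) & is.finite(a_l)
  if (any(!ok))
    message(sprintf("threshold_change: excluded %d subject(s) with a missing threshold estimate",
                    sum(!ok)))
  if (!any(ok))
    stop("no paired subjects with threshold estimates at both cutoffs")
  diffs <- (a_s - a_l)[ok]
  names(diffs) <- ids[ok]
  if (all(diffs == 0)) {
    p <- 1
    test_name <- "Wilcoxon signed rank (degenerate: all differences zero)"
  } else {
    p <- signed_rank_test(diffs, alternative = "greater")$p_value
    test_name <- "Wilcoxon signed rank (one-sided, location > 0)"
  }
  structure(
    list(n_subjects = length(diffs),
         n_excluded = sum(!ok),
         diffs = diffs,
         mean_diff = mean(diffs),
         median_diff = stats::median(diffs),
         p_value = p,
         test_name = test_name),
    class = "threshold_change_summary"
  )
}

#' @export
print.threshold_change_summary <- function(x, ...) {
  cat("Threshold change across dichotomizations (stricter - looser)\n")
  cat(sprintf("  n = %d paired subjects (%d excluded)\n",
              x$n_subjects, x$n_excluded))
  cat(sprintf("  mean change = %.4g, median change = %.4g\n",
              x$mean_diff, x$median_diff))
  cat(sprintf("  %s: p = %.4g\n", x$test_name, x$p_value))
  invisible(x)
}

#' Wilcoxon signed-rank test with an exact small-sample branch
#'
#' Tests a location shift of paired differences. Zero differences are
#' dropped by default (Wilcoxon convention; Pratt's zero-handling, which
#' ranks zeros before discarding their contribution, is available). The
#' null distribution of the positive-rank sum W+ is computed exactly — by
#' enumeration of all sign assignments of the (mid)ranks, handling ties —
#' when at most `exact_limit` nonzero differences remain, and by a normal
#' approximation whose variance `sum(rank^2)/4` carries the tie correction
#' otherwise (no continuity correction).
#'
#' @param diffs numeric vector of paired differences, not all zero.
#' @param alternative `"greater"` (location > 0) or `"two.sided"`.
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @param exact_limit largest number of nonzero differences for which the
#'   exact branch is used (default 20).
#' @return Object of class `"signed_rank_test"`: `statistic` (W+),
#'   `p_value`, `n_nonzero`, `exact`, `alternative`.
#' @examples
#' signed_rank_test(c(1, 2, 3, 4, 5))$p_value  # 1/32
#' @export
signed_rank_test <- function(diffs, alternative = c("greater", "two.sided"),
                             zeros = c("drop", "pratt"), exact_limit = 20L) {
  alternative <- match.arg(alternative)
  zeros <- match.arg(zeros)
  stopifnot(is.numeric(diffs), length(diffs) >= 1L, all(is.finite(diffs)))
  nz <- diffs != 0
  if (!any(nz))
    stop("signed-rank test undefined: all differences are zero")
  if (zeros == "drop") {
    d <- diffs[nz]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(diffs))
    d <- diffs[nz]
    r <- r_all[nz]
  }
  n <- length(d)
  w <- sum(r[d > 0])
  # midranks are multiples of 1/2: double them so the convolution is integer
  r2 <- as.integer(round(2 * r))
  if (n <= exact_limit) {
    S <- sum(r2)
    f <- numeric(S + 1)
    f[1] <- 1
    for (ri in r2)
      f <- (f + c(numeric(ri), f[seq_len(S + 1 - ri)])) / 2
    w2 <- as.integer(round(2 * w))
    p_ge <- sum(f[(w2 + 1):(S + 1)])
    p_le <- sum(f[seq_len(w2 + 1)])
    exact <- TRUE
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu) / sigma
    p_ge <- stats::pnorm(z, lower.tail = FALSE)
    p_le <- stats::pnorm(z)
    exact <- FALSE
  }
  p <- switch(alternative,
              greater = p_ge,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  structure(
    list(statistic = w, p_value = p, n_nonzero = n,
         exact = exact, alternative = alternative, zeros = zeros),
    class = "signed_rank_test"
  )
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank test (%s, %s branch, zeros: %s)\n",
              x$alternative, if (x$exact) "exact" else "normal-approximation",
              x$zeros))
  cat(sprintf("  W+ = %g on %d nonzero differences, p = %.4g\n",
              x$statistic, x$n_nonzero, x$p_value))
  invisible(x)
}
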