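#' 2x2 classification counts at one candidate threshold
#'
#' Cross-classifies the `t` visits of a paired series by whether the
#' objective outcome reaches the candidate threshold `a` (rows ">= a" /
#' "< a") against the dichotomized PRO (columns positive / negative).
#' Ties `x == a` are classified positive (the ">= a" row).
#'
#' @param series a [paired_series()].
#' @param a a single finite candidate threshold.
#' @return Named integer vector `c(tp, fp, fn, tn)` with
#'   `tp + fp + fn + tn == t`.
#' @examples
#' s <- paired_series("s1", c(5, 7, 9, 11, 12, 13, 14, 15, 16),
#'                    c(0, 0, 0, 1, 1, 1, 1, 1, 1))
#' threshold_counts(s, 5)   # tp 6, fp 3
#' threshold_counts(s, 10)  # tp 6, tn 3
#' @export
threshold_counts <- function(series, a) {
  stopifnot(inherits(series, "paired_series"),
            length(a) == 1L, is.finite(a))
  pos <- series$x >= a
  g1 <- series$g == 1L
  c(tp = sum(pos & g1),
    fp = sum(pos & !g1),
    fn = sum(!pos & g1),
    tn = sum(!pos & !g1))
}

#' Scan a paired series over a threshold grid
#'
#' Tabulates the 2x2 counts of [threshold_counts()] at every grid point and
#' records the agreement accuracy `R_j = (TP + TN)_j / t` — the fraction of
#' visits on which the dichotomized PRO agrees with the side of the
#' candidate threshold on which the objective outcome falls. The scan is the
#' intermediate object from which Q and the latent threshold are estimated.
#'
#' @param series a [paired_series()].
#' @param grid a [threshold_grid()].
#' @return An object of class `"threshold_scan"`: list with the grid points
#'   `a`, integer count vectors `tp`, `fp`, `fn`, `tn`, the agreement
#'   successes `successes = tp + tn`, accuracies `r = successes / t`, the
#'   number of visits `t` and subject metadata.
#' @examples
#' s <- paired_series("s1", c(5, 7, 9, 11, 12, 13, 14, 15, 16),
#'                    c(0, 0, 0, 1, 1, 1, 1, 1, 1))
#' g <- threshold_grid(c(5, 6, 8, 10, 11, 12, 13.5, 15, 16))
#' as.data.frame(threshold_scan(s, g))
#' @export
threshold_scan <- function(series, grid) {
  stopifnot(inherits(series, "paired_series"),
            inherits(grid, "threshold_grid"))
  pos <- outer(series$x, grid$points, ">=")
  g1 <- series$g == 1L
  tp <- as.integer(colSums(pos & g1))
  fp <- as.integer(colSums(pos & !g1))
  fn <- as.integer(colSums(!pos & g1))
  tn <- as.integer(colSums(!pos & !g1))
  succ <- tp + tn
  structure(
    list(a = grid$points,
         tp = tp, fp = fp, fn = fn, tn = tn,
         successes = succ,
         r = succ / series$t,
         t = series$t,
         subject_id = series$subject_id,
         scale_label = series$scale_label,
         n_unique_x = length(unique(series$x)),
         n_pos_g = sum(series$g == 1L)),
    class = "threshold_scan"
  )
}

#' @export
as.data.frame.threshold_scan <- function(x, ...) {
  data.frame(a = x$a, tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
             successes = x$successes, r = x$r)
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("Threshold scan for subject '%s' (t = %d visits, m = %d grid points)\n",
              x$subject_id, x$t, length(x$a)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Estimate the revealing-truth probability Q for one subject
#'
#' Under the `"max"` rule the estimate of Q is the maximum agreement
#' accuracy over the grid, `max_j R_j`, which is consistent for Q when
#' Q > 0.5 and the latent threshold lies in the grid; the latent threshold
#' is estimated as the median of the grid points tied at the maximum (mean
#' of the two middle points for an even tie count). Under the `"median"`
#' rule — appropriate for the no-association null Q = 0.5, where every
#' `R_j` is unbiased for Q — the estimate is the median of all `R_j`
#' values; the reported threshold is then the median of the grid points
#' whose accuracy is nearest that median, but it is not identified (there
#' is no threshold to find when the PRO is pure chance) and is flagged as
#' such.
#'
#' The sampling variance is `q(1 - q)/t` and the confidence interval is the
#' exact binomial (Clopper-Pearson) interval on the selected agreement
#' successes, both justified by the binomial behaviour of TP + TN at the
#' true threshold. Under the median rule the successes are rounded
#' (half up) to the nearest integer before the interval is formed.
#'
#' @param scan a [threshold_scan()].
#' @param rule `"max"` (default) or `"median"`.
#' @param level confidence level for the exact binomial interval
#'   (default 0.95).
#' @return An object of class `"q_estimate"`: list with `q_hat`, `a_hat`,
#'   `tie_points`, `successes`, `n_visits`, `variance`, `ci_low`,
#'   `ci_high`, `level`, `rule`, `a_identified`, `eligible` and subject
#'   metadata.
#' @examples
#' s <- paired_series("s1", c(5, 7, 9, 11, 12, 13, 14, 15, 16),
#'                    c(0, 0, 0, 1, 1, 1, 1, 1, 1))
#' g <- threshold_grid(c(5, 6, 8, 10, 11, 12, 13.5, 15, 16))
#' estimate_q(threshold_scan(s, g))  # q_hat = 1, a_hat = 10.5
#' @export
estimate_q <- function(scan, rule = c("max", "median"), level = 0.95) {
  rule <- match.arg(rule)
  stopifnot(inherits(scan, "threshold_scan"))
  if (length(scan$a) < 1L) stop("empty threshold scan")
  t <- scan$t
  if (rule == "max") {
    # exact integer comparison of successes avoids any floating tie ambiguity
    s_sel <- max(scan$successes)
    tie_points <- scan$a[scan$successes == s_sel]
    q_hat <- s_sel / t
    a_identified <- TRUE
  } else {
    q_hat <- stats::median(scan$r)
    s_sel <- as.integer(floor(q_hat * t + 0.5))
    d <- abs(scan$successes - q_hat * t)
    tie_points <- scan$a[d <= min(d) + 1e-12]
    a_identified <- FALSE
  }
  a_hat <- stats::median(tie_points)
  if (scan$n_unique_x == 1L || scan$n_pos_g %in% c(0L, t))
    warning(sprintf(paste0("degenerate data for subject '%s': all objective ",
                           "outcomes identical or all PRO responses identical; ",
                           "the threshold estimate is uninformative"),
                    scan$subject_id))
  ci <- exact_binom_ci(s_sel, t, level)
  structure(
    list(q_hat = q_hat,
         a_hat = a_hat,
         tie_points = tie_points,
         successes = s_sel,
         n_visits = t,
         variance = q_hat * (1 - q_hat) / t,
         ci_low = ci[[1]],
         ci_high = ci[[2]],
         level = level,
         rule = rule,
         a_identified = a_identified,
         eligible = scan$n_pos_g >= 1L && scan$n_unique_x >= 2L,
         subject_id = scan$subject_id,
         scale_label = scan$scale_label),
    class = "q_estimate"
  )
}

#' @export
print.q_estimate <- function(x, ...) {
  cat(sprintf("Revealing-truth probability estimate (%s rule) for subject '%s'%s\n",
              x$rule, x$subject_id,
              if (is.null(x$scale_label)) "" else paste0(" at ", x$scale_label)))
  cat(sprintf("  Q-hat = %.4f  (%d/%d agreements; %.0f%% exact CI %.4f-%.4f)\n",
              x$q_hat, x$successes, x$n_visits, 100 * x$level,
              x$ci_low, x$ci_high))
  cat(sprintf("  a-hat = %g%s", x$a_hat,
              if (x$a_identified) "" else "  [not identified under the median rule]"))
  if (x$a_identified && length(x$tie_points) > 1L)
    cat(sprintf("  (median of %d tied grid points: %s)",
                length(x$tie_points), paste(x$tie_points, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Interval obtained by inverting the binomial tail probabilities, written
#' in its beta-quantile closed form. The lower limit is 0 when there are no
#' successes and the upper limit is 1 when all trials succeed.
#'
#' @param successes number of successes, `0 <= successes <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level in (0, 1); default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' exact_binom_ci(8, 9)
#' @export
exact_binom_ci <- function(successes, n, level = 0.95) {
  if (length(successes) != 1L || length(n) != 1L ||
      !is.finite(successes) || !is.finite(n) ||
      successes != round(successes) || n != round(n) ||
      n < 1 || successes < 0 || successes > n)
    stop("'successes' must be an integer in [0, n], n >= 1")
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1)
    stop("'level' must lie strictly between 0 and 1")
  alpha <- 1 - level
  low <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1)
  high <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(low = low, high = high)
}

#' Binomial variance estimate of Q-hat
#'
#' `q(1 - q)/t`, valid because TP + TN is binomial with parameters `t` and
#' Q when the candidate threshold equals the subject's latent threshold.
#'
#' @param q_hat estimated probability in \[0, 1\].
#' @param t number of visits, `t >= 1`.
#' @return The variance estimate.
#' @examples
#' q_variance(0.5, 10)  # 0.025
#' @export
q_variance <- function(q_hat, t) {
  stopifnot(is.numeric(q_hat), all(q_hat >= 0 & q_hat <= 1),
            is.numeric(t), all(t >= 1))
  q_hat * (1 - q_hat) / t
}
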