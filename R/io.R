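# Shared reader: validated long-format data.frame from a CSV with columns
# subject_id, visit, x and g (binary) or pro (ordinal). Rows with a missing
# x or missing g/pro are dropped with a message; duplicate (subject, visit)
# rows are a hard error.
read_long <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit", "x")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) || !any(c("g", "pro") %in% names(df)))
    stop(sprintf("input must have columns subject_id, visit, x and g or pro; missing: %s",
                 paste(c(missing_cols,
                         if (!any(c("g", "pro") %in% names(df))) "g/pro"),
                       collapse = ", ")))
  resp <- if ("g" %in% names(df)) df$g else df$pro
  keep <- !is.na(df$x) & !is.na(resp) & !is.na(df$subject_id) & !is.na(df$visit)
  if (any(!keep))
    message(sprintf("read_long: dropped %d row(s) with missing values", sum(!keep)))
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no usable rows after dropping missing values")
  dup <- duplicated(df[, c("subject_id", "visit")])
  if (any(dup))
    stop(sprintf("duplicate (subject, visit) rows: %s",
                 paste(unique(sprintf("(%s, %s)", df$subject_id[dup],
                                      df$visit[dup])), collapse = ", ")))
  attr(df, "n_dropped_rows") <- sum(!keep)
  df
}

#' Read long-format paired data into per-subject series
#'
#' Reads a CSV with header columns `subject_id`, `visit`, `x` and either
#' `g` (binary, already dichotomized) or `pro` (raw ordinal score, which is
#' dichotomized at `dichotomize_at`). Visits are ordered by the `visit`
#' column, one series per subject. Rows with a missing `x` or response are
#' dropped with a logged count; duplicate (subject, visit) rows are an
#' error.
#'
#' @param path CSV path.
#' @param dichotomize_at optional integer cutoff applied to the `pro`
#'   column via [dichotomize()]; required when the file has `pro` but no
#'   `g`.
#' @param scale_range PROM scale range passed to [dichotomize()].
#' @return Named list of [paired_series()], one per subject, with
#'   attribute `n_dropped_rows`.
#' @export
read_paired_csv <- function(path, dichotomize_at = NULL,
                            scale_range = c(1L, 7L)) {
  df <- read_long(path)
  if (!is.null(dichotomize_at)) {
    if (!"pro" %in% names(df))
      stop("'dichotomize_at' given but the file has no 'pro' column")
    df$g <- dichotomize(df$pro, dichotomize_at, scale_range)
    label <- sprintf("PRO >= %d", as.integer(dichotomize_at))
  } else {
    if (!"g" %in% names(df))
      stop("file has a 'pro' column only: supply 'dichotomize_at'")
    if (!all(df$g %in% c(0, 1)))
      stop("column 'g' must be binary 0/1; use 'pro' + 'dichotomize_at' for raw scores")
    label <- NULL
  }
  ids <- unique(df$subject_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    sub <- sub[order(sub$visit), , drop = FALSE]
    paired_series(id, x = sub$x, g = sub$g, scale_label = label)
  })
  names(out) <- ids
  attr(out, "n_dropped_rows") <- attr(df, "n_dropped_rows")
  out
}

#' Estimate Q for every subject in a list of series
#'
#' @param series_list list of [paired_series()] (e.g. from
#'   [read_paired_csv()]).
#' @param grid a [threshold_grid()].
#' @param rule,level passed to [estimate_q()].
#' @return Named list of [estimate_q()] results.
#' @export
estimate_subjects <- function(series_list, grid, rule = "max", level = 0.95) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  out <- lapply(series_list, function(s)
    estimate_q(threshold_scan(s, grid), rule = rule, level = level))
  names(out) <- vapply(out, `[[`, character(1), "subject_id")
  out
}

#' Tidy per-subject estimate table
#'
#' @param estimates list of [estimate_q()] results.
#' @return A data.frame with one row per subject: `subject_id`,
#'   `scale_label`, `n_visits`, `q_hat`, `a_hat`, `ci_low`, `ci_high`,
#'   `variance`, `n_ties`, `eligible`.
#' @export
estimate_table <- function(estimates) {
  stopifnot(is.list(estimates),
            all(vapply(estimates, inherits, logical(1), "q_estimate")))
  do.call(rbind, lapply(estimates, function(e)
    data.frame(subject_id = e$subject_id,
               scale_label = if (is.null(e$scale_label)) NA_character_ else e$scale_label,
               n_visits = e$n_visits,
               q_hat = e$q_hat,
               a_hat = e$a_hat,
               ci_low = e$ci_low,
               ci_high = e$ci_high,
               variance = e$variance,
               n_ties = length(e$tie_points),
               eligible = e$eligible,
               row.names = NULL)))
}
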