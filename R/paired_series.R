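#' Repeated paired observations for one subject
#'
#' Bundles the `t` repeated pairs `(x_k, g_k)` observed for a single subject
#' across clinical visits: a continuous objective outcome `x` (e.g. change
#' from baseline in hemoglobin count, or letters gained on an ETDRS chart)
#' and the dichotomized patient-reported outcome `g` at one dichotomization
#' of the PROM scale. This is the unit of analysis for the revealing-truth
#' estimator: everything downstream is a per-visit tabulation of these pairs.
#'
#' @param subject_id a single label identifying the subject.
#' @param x numeric vector of objective outcomes, one per visit; all finite.
#' @param g binary (0/1) vector of dichotomized PRO responses, same length
#'   as `x`.
#' @param scale_label optional label for the dichotomization that produced
#'   `g`, e.g. `"PRO >= 5"`.
#'
#' @return An object of class `"paired_series"`: a list with elements
#'   `subject_id`, `x`, `g`, `t` (number of visits) and `scale_label`.
#'
#' @examples
#' s <- paired_series("subj1",
#'                    x = c(5, 7, 9, 11, 12, 13, 14, 15, 16),
#'                    g = c(0, 0, 0, 1, 1, 1, 1, 1, 1),
#'                    scale_label = "PRO >= 5")
#' s
#' @seealso [threshold_scan()], [estimate_q()], [dichotomize()]
#' @export
paired_series <- function(subject_id, x, g, scale_label = NULL) {
  if (length(subject_id) != 1L || is.na(subject_id))
    stop("'subject_id' must be a single non-missing label")
  x <- as.numeric(x)
  if (length(x) < 1L)
    stop("a paired series needs at least one visit")
  if (length(g) != length(x))
    stop(sprintf("'x' (length %d) and 'g' (length %d) must have equal length",
                 length(x), length(g)))
  if (!all(is.finite(x)))
    stop("all objective outcomes 'x' must be finite")
  g_num <- suppressWarnings(as.numeric(g))
  if (anyNA(g_num) || !all(g_num %in% c(0, 1)))
    stop("'g' must contain only 0/1 values")
  structure(
    list(subject_id = as.character(subject_id),
         x = x,
         g = as.integer(g_num),
         t = length(x),
         scale_label = scale_label),
    class = "paired_series"
  )
}

#' @export
print.paired_series <- function(x, ...) {
  cat(sprintf("Paired series for subject '%s' (%d visit%s%s)\n",
              x$subject_id, x$t, if (x$t == 1L) "" else "s",
              if (is.null(x$scale_label)) "" else paste0(", ", x$scale_label)))
  print(data.frame(visit = seq_len(x$t), x = x$x, g = x$g), row.names = FALSE)
  invisible(x)
}

#' Dichotomize ordinal PRO scores at a cutoff
#'
#' Maps raw ordinal PRO scores to the binary responses `g` used by the
#' estimator: `g = 1` when the score reaches the cutoff `z` (the event
#' "PRO >= z"), `g = 0` otherwise.
#'
#' @param pro_scores integer vector of raw ordinal PRO scores.
#' @param cutoff the dichotomization cutoff `z`; must lie within
#'   `scale_range`.
#' @param scale_range the declared range of the PROM scale
#'   (default `c(1, 7)`, a 7-point instrument).
#'
#' @return Integer 0/1 vector, same length as `pro_scores`.
#'
#' @examples
#' dichotomize(c(3, 5, 7), cutoff = 5)  # 0 1 1
#' @export
dichotomize <- function(pro_scores, cutoff, scale_range = c(1L, 7L)) {
  stopifnot(length(scale_range) == 2L, scale_range[1] < scale_range[2])
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff != round(cutoff) ||
      cutoff < scale_range[1] || cutoff > scale_range[2])
    stop(sprintf("'cutoff' must be an integer within the PROM scale range [%s, %s]",
                 scale_range[1], scale_range[2]))
  scores <- suppressWarnings(as.numeric(pro_scores))
  bad <- which(!is.finite(scores) | scores != round(scores) |
                 scores < scale_range[1] | scores > scale_range[2])
  if (length(bad))
    stop(sprintf("invalid PRO score at visit%s %s: scores must be integers in [%s, %s]",
                 if (length(bad) == 1L) "" else "s",
                 paste(bad, collapse = ", "),
                 scale_range[1], scale_range[2]))
  as.integer(scores >= cutoff)
}

#' Eligibility of a subject for population summaries
#'
#' A subject is eligible when the dichotomized PRO actually contains a
#' positive response and the objective outcomes take at least two distinct
#' values; otherwise the scan carries no information about the latent
#' threshold location.
#'
#' @param series a [paired_series()].
#' @return `TRUE` or `FALSE`.
#' @export
is_eligible <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  any(series$g == 1L) && length(unique(series$x)) >= 2L
}
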