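#' Pre-specified threshold searching grid
#'
#' The candidate latent thresholds `a_1 < ... < a_m` at which the paired
#' series is tabulated. The grid is fixed in advance from clinical knowledge
#' of the plausible range of the objective endpoint (e.g. the normal range
#' of hemoglobin concentration); it is not data-driven and does not change
#' with subject.
#'
#' @param points strictly increasing numeric vector of candidate thresholds,
#'   in the units of the objective outcome.
#' @return An object of class `"threshold_grid"`: list with `points` and
#'   `m` (number of grid points).
#' @examples
#' threshold_grid(c(5, 6, 8, 10, 11, 12, 13.5, 15, 16))
#' @seealso [threshold_grid_range()]
#' @export
threshold_grid <- function(points) {
  points <- as.numeric(points)
  if (length(points) < 1L)
    stop("a threshold grid needs at least one point")
  if (!all(is.finite(points)))
    stop("all grid points must be finite")
  if (length(points) > 1L && any(diff(points) <= 0))
    stop("grid points must be strictly increasing")
  structure(list(points = points, m = length(points)),
            class = "threshold_grid")
}

#' Build an evenly spaced threshold grid from a range
#'
#' Generates `min + j * step` for `j = 0, 1, ...` by integer index (so grid
#' points do not accumulate floating-point drift); the last point is the one
#' within half a step of `max`. The default simulation grid
#' `threshold_grid_range(-2, 5, 0.1)` has m = 71 points and contains
#' -0.3, 0.4 and 1.2 exactly up to one rounding of the index formula.
#'
#' @param min,max range endpoints, units of the objective outcome.
#' @param step positive increment; sets how precisely the latent threshold
#'   can be located.
#' @return A [threshold_grid()].
#' @examples
#' g <- threshold_grid_range(-2, 5, 0.1)
#' g$m  # 71
#' @export
threshold_grid_range <- function(min, max, step) {
  stopifnot(is.finite(min), is.finite(max), is.finite(step),
            step > 0, max >= min)
  j_max <- floor((max - min) / step + 0.5)
  threshold_grid(min + (0:j_max) * step)
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat(sprintf("Threshold grid: m = %d points in [%g, %g]\n",
              x$m, x$points[1], x$points[x$m]))
  invisible(x)
}
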