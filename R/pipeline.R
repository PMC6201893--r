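#' Configuration of a full PROM validation analysis
#'
#' Collects everything a study run needs: the input data, the pre-specified
#' threshold grid, the dichotomization cutoffs to analyse, the confidence
#' level, the minimum acceptable revealing-truth probability delta, the
#' estimator rule and the eligibility filter.
#'
#' @param input_path long-format CSV (see [read_paired_csv()]). When
#'   `cutoffs` is given the file must carry the raw `pro` column.
#' @param grid a [threshold_grid()].
#' @param cutoffs optional strictly increasing integer dichotomization
#'   cutoffs within `scale_range` (e.g. `c(5, 6, 7)`); `NULL` analyses the
#'   file's pre-dichotomized `g` column as a single unnamed cutoff.
#' @param ci_level confidence level in (0, 1), default 0.95.
#' @param delta minimum acceptable revealing-truth probability, default 0.5.
#' @param rule estimator rule, `"max"` or `"median"`.
#' @param filter_eligible apply the eligibility filter in population
#'   summaries (default `TRUE`).
#' @param scale_range PROM scale range, default `c(1, 7)`.
#' @param output_dir optional directory for the CSV reports of
#'   [run_pipeline()].
#' @return Object of class `"study_config"`.
#' @export
study_config <- function(input_path, grid, cutoffs = NULL,
                         ci_level = 0.95, delta = 0.5, rule = "max",
                         filter_eligible = TRUE, scale_range = c(1L, 7L),
                         output_dir = NULL) {
  stopifnot(inherits(grid, "threshold_grid"),
            length(ci_level) == 1L, ci_level > 0, ci_level < 1,
            length(delta) == 1L, is.finite(delta),
            rule %in% c("max", "median"))
  if (!is.null(cutoffs)) {
    cutoffs <- as.integer(cutoffs)
    if (length(cutoffs) < 1L || anyNA(cutoffs) ||
        (length(cutoffs) > 1L && any(diff(cutoffs) <= 0)) ||
        any(cutoffs < scale_range[1]) || any(cutoffs > scale_range[2]))
      stop(sprintf("'cutoffs' must be strictly increasing integers within [%s, %s]",
                   scale_range[1], scale_range[2]))
  }
  structure(
    list(input_path = input_path, grid = grid, cutoffs = cutoffs,
         ci_level = ci_level, delta = delta, rule = rule,
         filter_eligible = filter_eligible, scale_range = scale_range,
         output_dir = output_dir),
    class = "study_config"
  )
}

#' Run the full PROM validation pipeline
#'
#' For each dichotomization cutoff: reads the data, estimates Q and the
#' latent threshold per subject, and aggregates them into a population
#' summary tested against delta. When several cutoffs are analysed, the
#' responsiveness of the PROM is assessed for every consecutive cutoff pair
#' and for the extreme pair (stricter minus looser threshold shift, median
#' and one-sided signed-rank test). Writes CSV reports when the
#' configuration names an output directory; logs subject accounting to the
#' message stream.
#'
#' @param config a [study_config()].
#' @return (Invisibly) a list: `per_subject` (data.frame over all cutoffs),
#'   `estimates` (list by cutoff label of per-subject estimate lists),
#'   `population` (data.frame, one row per cutoff), `responsiveness`
#'   (data.frame of cutoff pairs, or `NULL`), `counts` (subject
#'   accounting).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cutoffs <- config$cutoffs
  labels <- if (is.null(cutoffs)) "g" else sprintf("PRO >= %d", cutoffs)

  estimates <- list()
  for (i in seq_along(labels)) {
    series <- tryCatch(
      read_paired_csv(config$input_path,
                      dichotomize_at = if (is.null(cutoffs)) NULL else cutoffs[i],
                      scale_range = config$scale_range),
      error = function(e) stop(sprintf("[read] %s", conditionMessage(e))))
    estimates[[labels[i]]] <- tryCatch(
      suppressWarnings(estimate_subjects(series, config$grid,
                                         rule = config$rule,
                                         level = config$ci_level)),
      error = function(e) stop(sprintf("[estimate] %s", conditionMessage(e))))
  }
  n_read <- length(estimates[[1]])

  per_subject <- do.call(rbind, lapply(estimates, estimate_table))
  rownames(per_subject) <- NULL

  population <- do.call(rbind, lapply(labels, function(lab) {
    ests <- estimates[[lab]]
    n_eligible <- sum(vapply(ests, `[[`, logical(1), "eligible"))
    n_used <- if (config$filter_eligible) n_eligible else length(ests)
    if (n_used == 0L)
      stop(sprintf("[aggregate] no eligible subjects at %s", lab))
    if (n_used == 1L) {
      # a single subject supports a per-subject estimate but no population CI
      message(sprintf("%s: only 1 eligible subject; population interval omitted", lab))
      one <- if (config$filter_eligible)
        Filter(function(e) isTRUE(e$eligible), ests)[[1]] else ests[[1]]
      return(data.frame(cutoff = lab, n_subjects = 1L,
                        n_filtered = length(ests) - 1L, mean_q = one$q_hat,
                        ci_low = NA_real_, ci_high = NA_real_,
                        level = config$ci_level, delta = config$delta,
                        passes = NA, row.names = NULL))
    }
    pop <- tryCatch(
      aggregate_q(ests, level = config$ci_level, delta = config$delta,
                  filter_eligible = config$filter_eligible),
      error = function(e) stop(sprintf("[aggregate] %s", conditionMessage(e))))
    message(sprintf("%s: read %d subjects = %d eligible + %d filtered",
                    lab, n_read, pop$n_subjects, pop$n_filtered))
    data.frame(cutoff = lab, n_subjects = pop$n_subjects,
               n_filtered = pop$n_filtered, mean_q = pop$mean_q,
               ci_low = pop$ci_low, ci_high = pop$ci_high,
               level = pop$level, delta = pop$delta, passes = pop$passes,
               row.names = NULL)
  }))

  responsiveness <- NULL
  if (length(labels) >= 2L) {
    pairs <- cbind(seq_len(length(labels) - 1L) + 1L,
                   seq_len(length(labels) - 1L))
    if (length(labels) > 2L)
      pairs <- rbind(pairs, c(length(labels), 1L))
    responsiveness <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      hi <- pairs[k, 1]; lo <- pairs[k, 2]
      e_hi <- estimates[[hi]]
      e_lo <- estimates[[lo]]
      if (config$filter_eligible) {
        keep_hi <- vapply(e_hi, `[[`, logical(1), "eligible")
        keep_lo <- vapply(e_lo, `[[`, logical(1), "eligible")
        common <- intersect(names(e_hi)[keep_hi], names(e_lo)[keep_lo])
      } else {
        common <- intersect(names(e_hi), names(e_lo))
      }
      n_dropped <- length(union(names(e_hi), names(e_lo))) - length(common)
      if (n_dropped > 0L)
        message(sprintf("responsiveness %s vs %s: %d subject(s) without estimates at both cutoffs",
                        labels[hi], labels[lo], n_dropped))
      if (length(common) < 1L)
        stop(sprintf("[responsiveness] no paired subjects for %s vs %s",
                     labels[hi], labels[lo]))
      tc <- tryCatch(
        threshold_change(e_hi[common], e_lo[common]),
        error = function(e) stop(sprintf("[responsiveness] %s",
                                         conditionMessage(e))))
      data.frame(from = labels[lo], to = labels[hi],
                 n_subjects = tc$n_subjects, mean_change = tc$mean_diff,
                 median_change = tc$median_diff, p_value = tc$p_value,
                 row.names = NULL)
    }))
  }

  out <- list(per_subject = per_subject, estimates = estimates,
              population = population, responsiveness = responsiveness,
              counts = list(n_read = n_read,
                            n_eligible = population$n_subjects,
                            n_filtered = population$n_filtered))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_subject,
                     file.path(config$output_dir, "per_subject_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(population,
                     file.path(config$output_dir, "population_summary.csv"),
                     row.names = FALSE)
    if (!is.null(responsiveness))
      utils::write.csv(responsiveness,
                       file.path(config$output_dir, "responsiveness.csv"),
                       row.names = FALSE)
    message(sprintf("reports written to %s", config$output_dir))
  }
  invisible(out)
}
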