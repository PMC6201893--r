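# Toy data: 9 repeated (x, g) pairs for one subject, with the 9-point
# pre-specified grid; the two samples differ only in the 2nd PRO response.
toy_series_1 <- function() {
  paired_series("toy1",
                x = c(5, 7, 9, 11, 12, 13, 14, 15, 16),
                g = c(0, 0, 0, 1, 1, 1, 1, 1, 1),
                scale_label = "PRO >= 5")
}

toy_series_2 <- function() {
  paired_series("toy2",
                x = c(5, 7, 9, 11, 12, 13, 14, 15, 16),
                g = c(0, 1, 0, 1, 1, 1, 1, 1, 1),
                scale_label = "PRO >= 5")
}

toy_grid <- function() {
  threshold_grid(c(5, 6, 8, 10, 11, 12, 13.5, 15, 16))
}

# Random paired series with no structure (for property tests).
random_series <- function(t, id = "rnd") {
  paired_series(id,
                x = round(stats::runif(t, -3, 3), 2),
                g = stats::rbinom(t, 1, 0.5))
}

# A q_estimate whose threshold estimate is exactly `a` (single-point grid,
# perfectly separated series): lets inference tests control a_hat directly.
make_estimate_at <- function(id, a) {
  s <- paired_series(id, x = c(a - 1, a + 1), g = c(0, 1))
  estimate_q(threshold_scan(s, threshold_grid(a)))
}
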