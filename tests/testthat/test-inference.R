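test_that("population mean and t-interval match the closed form", {
  # two subjects, q_hats 0.6 and 1.0: mean 0.8, half-width qt(.975, 1) * se
  e1 <- estimate_q(threshold_scan(
    paired_series("A", c(1, 2, 3, 4, 5), c(1, 0, 0, 1, 0)),
    threshold_grid(3.5)))  # 3/5 agreements
  e2 <- estimate_q(threshold_scan(
    paired_series("B", c(1, 2, 3, 4, 5), c(0, 0, 0, 1, 1)),
    threshold_grid(3.5)))  # 5/5
  expect_equal(e1$q_hat, 0.6)
  expect_equal(e2$q_hat, 1.0)
  pop <- aggregate_q(list(e1, e2), level = 0.95, delta = 0.5,
                     filter_eligible = FALSE)
  half <- stats::qt(0.975, df = 1) * stats::sd(c(0.6, 1.0)) / sqrt(2)
  expect_equal(pop$mean_q, 0.8)
  expect_equal(pop$ci_low, 0.8 - half)
  expect_equal(pop$ci_high, 0.8 + half)
  expect_false(pop$passes)  # t(1) interval is far too wide to clear 0.5
})

test_that("degenerate identical estimates give a zero-width interval", {
  ests <- lapply(c("A", "B", "C"), function(id)
    estimate_q(threshold_scan(
      paired_series(id, c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 1)),
      threshold_grid(3.5))))  # each 4/5 = 0.8
  pop <- aggregate_q(ests, delta = 0.75)
  expect_equal(pop$mean_q, 0.8)
  expect_equal(pop$ci_low, 0.8)
  expect_equal(pop$ci_high, 0.8)
  expect_true(pop$passes)
  expect_false(aggregate_q(ests, delta = 0.8)$passes)  # strict inequality
})

test_that("aggregation is order-invariant and guards its inputs", {
  set.seed(11)
  ests <- lapply(1:6, function(i) {
    g <- c(stats::rbinom(5, 1, 0.5), 1L)  # guaranteed one positive PRO
    s <- paired_series(paste0("S", i), x = seq(-2, 2, length.out = 6), g = g)
    estimate_q(threshold_scan(s, threshold_grid(c(-1, 0, 1))))
  })
  p1 <- aggregate_q(ests)
  p2 <- aggregate_q(rev(ests))
  expect_equal(p1$mean_q, p2$mean_q)
  expect_equal(p1$ci_low, p2$ci_low)
  expect_error(aggregate_q(ests[1]), "at least 2")
  mixed <- ests
  mixed[[1]]$scale_label <- "PRO >= 5"
  mixed[[2]]$scale_label <- "PRO >= 6"
  expect_error(aggregate_q(mixed), "mix")
})

test_that("the eligibility filter drops uninformative subjects", {
  good <- lapply(c("A", "B"), function(id)
    estimate_q(threshold_scan(paired_series(id, c(1, 2, 3), c(0, 1, 1)),
                              threshold_grid(1.5))))
  bad <- suppressWarnings(estimate_q(threshold_scan(
    paired_series("C", c(2, 2, 2), c(1, 1, 1)), threshold_grid(1.5))))
  pop <- aggregate_q(c(good, list(bad)))
  expect_identical(pop$n_subjects, 2L)
  expect_identical(pop$n_filtered, 1L)
})

test_that("threshold changes pair by subject and flip under swapping", {
  strict <- lapply(c(A = 3, B = 5, C = 4), function(a) NULL)
  strict <- mapply(make_estimate_at, c("A", "B", "C"), c(3, 5, 4),
                   SIMPLIFY = FALSE)
  loose <- mapply(make_estimate_at, c("C", "A", "B"), c(1, 2, 2),
                  SIMPLIFY = FALSE)  # deliberately different order
  tc <- threshold_change(strict, loose)
  expect_identical(tc$n_subjects, 3L)
  expect_equal(unname(tc$diffs[c("A", "B", "C")]), c(1, 3, 3))
  expect_equal(tc$median_diff, 3)
  swapped <- threshold_change(loose, strict)
  expect_equal(unname(swapped$diffs), -unname(tc$diffs))
  expect_error(
    threshold_change(strict, mapply(make_estimate_at, c("A", "B", "D"),
                                    c(1, 1, 1), SIMPLIFY = FALSE)),
    "not paired")
})

test_that("all-zero threshold changes are a non-significant no-shift result", {
  strict <- mapply(make_estimate_at, c("A", "B"), c(2, 3), SIMPLIFY = FALSE)
  tc <- threshold_change(strict, strict)
  expect_equal(tc$median_diff, 0)
  expect_equal(tc$p_value, 1)
})

test_that("six equal positive shifts give the exact 1/64 p-value", {
  strict <- mapply(make_estimate_at, paste0("S", 1:6), (1:6) + 9,
                   SIMPLIFY = FALSE)
  loose <- mapply(make_estimate_at, paste0("S", 1:6), (1:6) + 0,
                  SIMPLIFY = FALSE)
  tc <- threshold_change(strict, loose)
  expect_equal(unname(tc$diffs), rep(9, 6))
  expect_equal(tc$p_value, 1 / 64)
})

test_that("signed-rank exact branch matches enumeration, with and without ties", {
  expect_equal(signed_rank_test(1)$p_value, 0.5)
  expect_equal(signed_rank_test(c(1, 2, 3, 4, 5))$p_value, 1 / 32)
  expect_equal(signed_rank_test(c(-1, 2, 3))$p_value,
               oracle_signed_rank_greater(c(-1, 2, 3)))
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(2:10, 1)
    d <- sample(c(-3:-1, 1:3), n, replace = TRUE)  # heavy ties
    expect_equal(signed_rank_test(d)$p_value, oracle_signed_rank_greater(d))
  }
})

test_that("signed-rank agrees with stats::wilcox.test on tie-free data", {
  set.seed(31)
  for (rep in 1:10) {
    d <- round(stats::rnorm(8), 6)
    expect_equal(signed_rank_test(d)$p_value,
                 stats::wilcox.test(d, alternative = "greater",
                                    exact = TRUE)$p.value)
    expect_equal(signed_rank_test(d, alternative = "two.sided")$p_value,
                 stats::wilcox.test(d, exact = TRUE)$p.value)
  }
  # large-sample branch vs the tie-corrected normal approximation
  d <- round(stats::rnorm(40), 1)
  expect_equal(signed_rank_test(d)$p_value,
               stats::wilcox.test(d, alternative = "greater",
                                  exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("signed-rank zero handling: drop default, Pratt option, all-zero error", {
  d <- c(0, 0, 1, 2, -3)
  expect_identical(signed_rank_test(d)$n_nonzero, 3L)
  pr <- signed_rank_test(d, zeros = "pratt")
  expect_identical(pr$n_nonzero, 3L)
  expect_false(isTRUE(all.equal(pr$p_value, signed_rank_test(d)$p_value)))
  expect_error(signed_rank_test(c(0, 0)), "all differences are zero")
})

test_that("signed-rank one-sided type-I error is controlled under the null", {
  set.seed(41)
  n_sim <- 400
  rej <- replicate(n_sim, {
    d <- stats::rnorm(12)
    signed_rank_test(d)$p_value <= 0.05
  })
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(mean(rej), 0.05 + 3 * se)
})
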