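test_that("2x2 counts match the toy example rows, ties counted positive", {
  s1 <- toy_series_1()
  expect_identical(threshold_counts(s1, 5.0),
                   c(tp = 6L, fp = 3L, fn = 0L, tn = 0L))
  expect_identical(threshold_counts(s1, 10.0),
                   c(tp = 6L, fp = 0L, fn = 0L, tn = 3L))
  # x == a falls in the ">= a" row: x = 11 with g = 1 is a true positive
  expect_identical(threshold_counts(s1, 11.0)[["tp"]], 6L)
  # everything below the threshold and negative is a true negative
  s0 <- paired_series("z", c(1, 2, 3), c(0, 0, 0))
  expect_identical(threshold_counts(s0, 10),
                   c(tp = 0L, fp = 0L, fn = 0L, tn = 3L))
})

test_that("the scan reproduces both printed accuracy columns", {
  g <- toy_grid()
  sc1 <- threshold_scan(toy_series_1(), g)
  sc2 <- threshold_scan(toy_series_2(), g)
  expect_equal(round(sc1$r, 2),
               c(0.67, 0.78, 0.89, 1.00, 1.00, 0.89, 0.67, 0.56, 0.44))
  expect_equal(round(sc2$r, 2),
               c(0.78, 0.89, 0.78, 0.89, 0.89, 0.78, 0.56, 0.44, 0.33))
  expect_identical(sc2$successes, c(7L, 8L, 7L, 8L, 8L, 7L, 5L, 4L, 3L))
})

test_that("counts are conserved and boundary counts are monotone along the grid", {
  set.seed(101)
  for (rep in 1:25) {
    s <- random_series(sample(1:8, 1))
    grid <- threshold_grid(sort(stats::runif(sample(1:12, 1), -4, 4)))
    sc <- threshold_scan(s, grid)
    expect_true(all(sc$tp + sc$fp + sc$fn + sc$tn == s$t))
    expect_true(all(diff(sc$tp + sc$fp) <= 0))  # x >= a shrinks as a grows
    expect_true(all(diff(sc$fn + sc$tn) >= 0))
    expect_equal(sc$r, (sc$tp + sc$tn) / s$t)
  }
})

test_that("max rule reproduces the toy estimates and their tie medians", {
  g <- toy_grid()
  e1 <- estimate_q(threshold_scan(toy_series_1(), g))
  expect_equal(e1$q_hat, 1.00)
  expect_equal(e1$tie_points, c(10, 11))
  expect_equal(e1$a_hat, 10.5)  # even tie count: mean of the two middle points
  expect_identical(e1$successes, 9L)
  expect_equal(e1$variance, 0)

  e2 <- estimate_q(threshold_scan(toy_series_2(), g))
  expect_equal(e2$q_hat, 8 / 9)
  expect_equal(round(e2$q_hat, 2), 0.89)
  expect_equal(e2$tie_points, c(6, 10, 11))
  expect_equal(e2$a_hat, 10)
  expect_equal(e2$variance, (8 / 9) * (1 / 9) / 9)
})

test_that("perfect separation at a bracketed cutpoint recovers q = 1", {
  set.seed(7)
  for (rep in 1:20) {
    x <- sort(stats::runif(6, -2, 2))
    cutpoint <- mean(x[3:4])  # strictly between two distinct x values
    s <- paired_series("p", x, as.integer(x >= cutpoint))
    grid <- threshold_grid(sort(c(stats::runif(8, -3, 3), cutpoint)))
    e <- estimate_q(threshold_scan(s, grid))
    expect_equal(e$q_hat, 1)
    expect_true(min(e$tie_points) <= cutpoint && cutpoint <= max(e$tie_points))
  }
})

test_that("max rule agrees with brute-force enumeration on random series", {
  set.seed(202)
  for (rep in 1:50) {
    s <- random_series(sample(1:8, 1))
    pts <- sort(stats::runif(sample(1:12, 1), -4, 4))
    e <- suppressWarnings(estimate_q(threshold_scan(s, threshold_grid(pts))))
    o <- oracle_estimate_max(s$x, s$g, pts)
    expect_equal(e$q_hat, o$q)
    expect_equal(e$a_hat, o$a)
  }
})

test_that("median rule: flip symmetry, ordering bounds, and CI rounding", {
  set.seed(303)
  for (rep in 1:20) {
    s <- random_series(sample(2:8, 1))
    grid <- threshold_grid(sort(stats::runif(sample(2:12, 1), -4, 4)))
    sc <- threshold_scan(s, grid)
    e_max <- suppressWarnings(estimate_q(sc, rule = "max"))
    e_med <- suppressWarnings(estimate_q(sc, rule = "median"))
    expect_gte(e_max$q_hat, e_med$q_hat)
    expect_gte(e_med$q_hat, min(sc$r))
    expect_false(e_med$a_identified)
    expect_true(e_max$a_identified)
    # replacing g by 1 - g maps every r to 1 - r, so the median flips
    s_flip <- paired_series(s$subject_id, s$x, 1L - s$g)
    e_flip <- suppressWarnings(estimate_q(threshold_scan(s_flip, grid), rule = "median"))
    expect_equal(e_flip$q_hat, 1 - e_med$q_hat)
  }
  # even grid count: median is the mean of the two central accuracies
  s <- paired_series("even", c(1, 2, 3, 4), c(0, 0, 1, 1))
  sc <- threshold_scan(s, threshold_grid(c(0.5, 2.5, 3.5, 4.5)))
  e <- estimate_q(sc, rule = "median")
  expect_equal(e$q_hat, mean(sort(sc$r)[2:3]))
  expect_identical(e$successes, as.integer(floor(e$q_hat * 4 + 0.5)))
})

test_that("degenerate series are estimable but flagged", {
  g <- threshold_grid(c(1, 2))
  expect_warning(estimate_q(threshold_scan(
    paired_series("d1", c(2, 2, 2), c(0, 1, 0)), g)), "degenerate")
  expect_warning(estimate_q(threshold_scan(
    paired_series("d2", c(1, 2, 3), c(1, 1, 1)), g)), "degenerate")
  # all-identical x leaves nothing to locate a threshold with: ineligible
  e1 <- suppressWarnings(estimate_q(threshold_scan(
    paired_series("d1", c(2, 2, 2), c(0, 1, 0)), g)))
  expect_false(e1$eligible)
  # all-positive PRO still "contains the dichotomized value": eligible
  e2 <- suppressWarnings(estimate_q(threshold_scan(
    paired_series("d2", c(1, 2, 3), c(1, 1, 1)), g)))
  expect_true(e2$eligible)
})

test_that("exact binomial CI matches its closed form, boundaries and oracles", {
  expect_equal(exact_binom_ci(0, 10)[["low"]], 0)
  expect_equal(exact_binom_ci(10, 10)[["high"]], 1)
  ci <- exact_binom_ci(8, 9)
  expect_equal(unname(ci), oracle_cp_ci(8, 9), tolerance = 1e-8)
  # independent route: stats::binom.test inverts the same tails
  for (s in c(1, 3, 5, 9)) {
    bt <- stats::binom.test(s, 9)$conf.int
    expect_equal(unname(exact_binom_ci(s, 9)), as.numeric(bt), tolerance = 1e-10)
  }
  expect_error(exact_binom_ci(5, 4), "successes")
  expect_error(exact_binom_ci(2, 9, level = 1), "level")
})

test_that("variance estimate is q(1-q)/t", {
  expect_equal(q_variance(0.5, 10), 0.025)
  expect_equal(q_variance(1.0, 9), 0)
  expect_equal(round(q_variance(0.89, 9), 4), 0.0109)
})

test_that("q_estimate invariants hold on random inputs", {
  set.seed(404)
  for (rep in 1:20) {
    s <- random_series(sample(2:8, 1))
    grid <- threshold_grid(sort(stats::runif(5, -4, 4)))
    e <- suppressWarnings(estimate_q(threshold_scan(s, grid)))
    expect_equal(e$q_hat, e$successes / e$n_visits)
    expect_true(e$ci_low <= e$q_hat && e$q_hat <= e$ci_high)
    expect_equal(e$variance, e$q_hat * (1 - e$q_hat) / e$n_visits)
  }
})
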