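test_that("binning uses half-open 10-ms bins anchored at zero", {
  b <- bin_srt(c(119.999, 120, 125), c(TRUE, TRUE, FALSE))
  expect_equal(b$n_correct[b$bin_left == 110], 1)
  expect_equal(b$n_correct[b$bin_left == 120], 1)
  expect_equal(b$n_incorrect[b$bin_left == 120], 1)
  expect_equal(nrow(bin_srt(numeric(0), logical(0))), 0)
  set.seed(41)
  srt <- runif(1000, 80, 400)
  correct <- runif(1000) < 0.7
  b <- bin_srt(srt, correct)
  # brute-force histogram
  for (edge in sample(b$bin_left, 20)) {
    expect_equal(b$n_correct[b$bin_left == edge],
                 sum(correct & srt >= edge & srt < edge + 10))
  }
  expect_equal(sum(b$n_correct) + sum(b$n_incorrect), 1000)
  expect_error(bin_srt(100, TRUE, width_ms = 0), "width")
})

test_that("per-bin chi-square matches hand arithmetic with a directional gate", {
  expect_false(chi2_bin_test(5, 5))       # chi2 = 0
  expect_true(chi2_bin_test(9, 1))        # chi2 = 6.4 > 3.841
  expect_false(chi2_bin_test(1, 9))       # same chi2, errors dominate
  expect_false(chi2_bin_test(0, 0))       # empty bin
  # vectorised
  expect_equal(chi2_bin_test(c(9, 5, 1), c(1, 5, 9)),
               c(TRUE, FALSE, FALSE))
  # Yates variant is more conservative
  expect_true(chi2_bin_test(10, 2))
  expect_equal(unname((10 - 2 - 1)^2 / 12 >= qchisq(0.95, 1)),
               unname(chi2_bin_test(10, 2, yates = TRUE)))
})

test_that("chi-square false-positive rate at 50/50 truth stays near alpha", {
  set.seed(42)
  nc <- rbinom(10000, 20, 0.5)
  fp <- mean(chi2_bin_test(nc, 20 - nc))
  expect_lte(fp, 0.05 + 0.01)
})

test_that("minimum SRT: constructive fixtures and exhaustive-scan oracle", {
  # five 10-correct bins from 120 ms, nothing earlier
  b <- bin_srt(rep(seq(125, 165, 10), each = 10), rep(TRUE, 50))
  expect_equal(minimum_srt(b)$min_srt_ms, 120)
  # run of only 4 significant bins: undefined
  b4 <- bin_srt(rep(seq(125, 155, 10), each = 10), rep(TRUE, 40))
  expect_true(is.na(minimum_srt(b4)$min_srt_ms))
  # all bins 5 vs 5: undefined
  b55 <- bin_srt(rep(seq(105, 295, 10), each = 10),
                 rep(c(TRUE, FALSE), 100))
  expect_true(is.na(minimum_srt(b55)$min_srt_ms))
  expect_error(minimum_srt(b, k = 0), "k")
  set.seed(43)
  for (i in 1:300) {
    b <- random_binned()
    expect_identical(minimum_srt(b)$min_srt_ms, oracle_min_srt(b))
  }
})

test_that("cumulative accuracy time-course matches its defining counts", {
  tr <- data.frame(srt_ms = c(100, 150, 200), correct = c(TRUE, FALSE, TRUE))
  tc <- accuracy_timecourse(tr)
  expect_equal(tc$cum_accuracy, c(1, 1 / 2, 2 / 3))
  expect_equal(tc$display, c(FALSE, TRUE, TRUE))
  # all-correct: constant 1
  expect_true(all(accuracy_timecourse(
    data.frame(srt_ms = 100:110, correct = TRUE))$cum_accuracy == 1))
  # final value closes on the overall accuracy; spot values equal
  # brute-force counts
  set.seed(44)
  tr <- data.frame(srt_ms = runif(500, 80, 400), correct = runif(500) < 0.7)
  tc <- accuracy_timecourse(tr)
  expect_equal(tc$cum_accuracy[500], mean(tr$correct))
  for (t0 in c(150, 200, 300)) {
    expect_equal(tc$cum_accuracy[max(which(tc$time_ms <= t0))],
                 mean(tr$correct[tr$srt_ms <= t0]))
  }
  expect_error(accuracy_timecourse(data.frame(srt_ms = numeric(0),
                                              correct = logical(0))),
               "no trials")
})

test_that("bootstrap percentile interval behaves on analytic cases", {
  set.seed(45)
  # constant statistic
  ci <- bootstrap_ci(function(d) 3.7, rnorm(50), n_boot = 100)
  expect_equal(c(ci$lower, ci$upper), c(3.7, 3.7))
  # degenerate sample
  ci <- bootstrap_ci(mean, rep(2, 30), n_boot = 100)
  expect_equal(c(ci$lower, ci$upper), c(2, 2))
  # mean of N(0,1), n = 200: covers 0, width near 2 * 1.96 / sqrt(200)
  x <- rnorm(200)
  ci <- bootstrap_ci(mean, x, n_boot = 500)
  expect_lt(ci$lower, mean(x))
  expect_gt(ci$upper, mean(x))
  expect_lt(abs((ci$upper - ci$lower) - 2 * 1.96 / sqrt(200)),
            0.2 * 2 * 1.96 / sqrt(200))
  # undefined resample statistics are counted, not dropped silently
  ci <- bootstrap_ci(function(d) if (mean(d) > 0) mean(d) else NA,
                     rnorm(20), n_boot = 200)
  expect_equal(ci$n_undefined, sum(is.na(ci$boot_stats)))
  expect_error(bootstrap_ci(mean, 1:5, n_boot = 1), "n_boot")
})

test_that("median SRT uses the midpoint convention", {
  expect_equal(median_srt(c(100, 200, 300)), 200)
  expect_equal(median_srt(c(100, 200)), 150)
  set.seed(46)
  x <- runif(101, 80, 400)
  expect_equal(median_srt(x), sort(x)[51])
  expect_error(median_srt(numeric(0)), "no SRTs")
})

test_that("minimum SRT under a time-homogeneous Bernoulli process", {
  # p = 0.5: undefined; min SRT decreases stochastically as p -> 1
  set.seed(47)
  mins <- sapply(c(0.5, 0.7, 0.9), function(p) {
    replicate(50, {
      srt <- runif(500, 100, 400)
      minimum_srt(bin_srt(srt, runif(500) < p))$min_srt_ms
    })
  })
  expect_gt(mean(is.na(mins[, 1])), 0.9)
  expect_lt(mean(is.na(mins[, 3])), 0.1)
  expect_lt(mean(mins[, 3], na.rm = TRUE), mean(mins[, 2], na.rm = TRUE))
})

test_that("effective mask duration subtracts the afferent-plus-motor overhead", {
  expect_equal(effective_mask_duration(125), 35)
  expect_equal(effective_mask_duration(160, overhead_ms = 90), 70)
})
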