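test_that("anticipation cutoff is strict at 70 ms", {
  tr <- data.frame(srt_ms = c(69.9, 70, 70.1))
  out <- flag_fast_outliers(tr)
  expect_equal(out$excluded_fast, c(TRUE, FALSE, FALSE))
  set.seed(31)
  x <- runif(1000, 50, 150)
  out <- flag_fast_outliers(data.frame(srt_ms = x))
  expect_equal(sum(out$excluded_fast), sum(x < 70))
})

test_that("medcouple: symmetry, invariance and tie handling", {
  expect_equal(medcouple(c(1, 2, 3)), 0)
  expect_equal(medcouple(c(1, 2, 2, 2, 3)), 0)
  set.seed(32)
  x <- rlnorm(50)
  mc <- medcouple(x)
  expect_gt(mc, 0)
  expect_true(mc <= 1)
  # location-scale invariance
  expect_equal(medcouple(3 * x + 10), mc, tolerance = 1e-12)
  expect_error(medcouple(c(1, 2)), "at least 3")
})

test_that("medcouple agrees exactly with the all-pairs brute force", {
  set.seed(33)
  for (i in 1:60) {
    n <- sample(3:60, 1)
    x <- switch(1 + i %% 3,
                rnorm(n), rlnorm(n), rexp(n))
    expect_equal(medcouple(x), oracle_medcouple(x), tolerance = 1e-12)
  }
  # with ties at the median
  expect_equal(medcouple(c(1, 5, 5, 5, 9, 12)),
               oracle_medcouple(c(1, 5, 5, 5, 9, 12)), tolerance = 1e-12)
})

test_that("adjusted fences reduce to Tukey at MC = 0 and widen under skew", {
  x <- c(1, 2, 3, 4, 5, 6, 7)  # symmetric: MC = 0
  f <- adjusted_boxplot_fences(x)
  q <- quantile(x, c(0.25, 0.75), type = 8, names = FALSE)
  expect_equal(unname(f), c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q)))
  set.seed(34)
  y <- rlnorm(200)
  fy <- adjusted_boxplot_fences(y)
  qy <- quantile(y, c(0.25, 0.75), type = 8, names = FALSE)
  expect_gt(fy["upper"], qy[2] + 1.5 * diff(qy))  # e^(3 MC) > 1
  expect_warning(adjusted_boxplot_fences(rep(5, 10)), "degenerate")
})

test_that("slow-outlier flags equal the brute-force fence rule per cell", {
  set.seed(35)
  tr <- data.frame(observer = rep(c("a", "b"), each = 50),
                   condition = "osm",
                   srt_ms = c(rlnorm(50, 5, 0.3), rlnorm(50, 5.5, 0.3)))
  tr <- flag_fast_outliers(tr)
  out <- flag_slow_outliers(tr)
  for (obs in c("a", "b")) {
    idx <- tr$observer == obs & !tr$srt_ms < 70
    up <- adjusted_boxplot_fences(tr$srt_ms[idx])["upper"]
    expect_equal(out$excluded_slow[idx], tr$srt_ms[idx] > up)
  }
})

test_that("flagged set is invariant to input row order", {
  set.seed(36)
  tr <- data.frame(observer = sample(c("a", "b"), 200, TRUE),
                   condition = sample(c("osm", "common_offset"), 200, TRUE),
                   srt_ms = rlnorm(200, 5.2, 0.4))
  out1 <- preprocess_trials(tr)
  perm <- sample(nrow(tr))
  out2 <- preprocess_trials(tr[perm, ])
  expect_equal(out2$analyzable[order(perm)], out1$analyzable)
})

test_that("stability selection excludes exactly the pre-stabilisation trials", {
  fx <- fixture_experiment()
  ex <- fx$ex
  tr <- fx$trials
  for (obs in c("obs1", "obs3")) {
    for (cond in c("common_offset", "osm")) {
      fs <- quest_first_stable(ex$staircases[[obs]][[cond]])
      cell <- tr[tr$observer == obs & tr$condition == cond, ]
      expect_equal(sum(cell$excluded_unstable), fs - 1L)
      expect_true(all(cell$excluded_unstable[seq_len(fs - 1L)]))
    }
  }
  expect_error(select_stable_trials(tr, list()), "missing staircase")
  # overall retention on the default design matches the empirical scale
  expect_gte(mean(tr$analyzable), 0.85)
})

test_that("trial table round-trips through CSV and errors name the column", {
  fx <- fixture_experiment()
  tr <- utils::head(fx$ex$trials, 100)
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$srt_ms, tr$srt_ms)
  expect_equal(back$correct, tr$correct)
  expect_equal(back$condition, tr$condition)
  # missing required column
  bad <- tr[, setdiff(names(tr), "correct")]
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_trials(path2), "correct")
  # nonstandard headers via the column map, case-insensitively
  odd <- tr
  names(odd)[names(odd) == "srt_ms"] <- "RT"
  names(odd)[names(odd) == "correct"] <- "Hit"
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(odd, path3, row.names = FALSE)
  remapped <- read_trials(path3, column_map = c(srt_ms = "rt", correct = "hit"))
  expect_equal(remapped$srt_ms, tr$srt_ms)
})

test_that("saccade detection recovers constructed events", {
  # fixation-only noise: no event
  set.seed(37)
  quiet <- synthesize_gaze_trace(150, noise_sd = 0.005)
  quiet$x_deg <- rnorm(nrow(quiet), 0, 0.005)  # strip the saccade
  expect_equal(nrow(detect_saccades(quiet)), 0)
  # noiseless 10 degree saccade at 150 ms: one event, onset within ~1
  # sample of truth (3-sample smoothing can shift it one sample early)
  tr <- synthesize_gaze_trace(150, noise_sd = 0)
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_ms - 150), 2.001)
  expect_gt(ev$peak_velocity_deg_s, 100)
  expect_equal(ev$direction, "right")
  # sub-threshold wiggle: crosses the velocity criterion but moves less
  # than the motion threshold
  wig <- synthesize_gaze_trace(150, noise_sd = 0, amplitude_deg = 0.1,
                               saccade_duration_ms = 8)
  expect_equal(nrow(detect_saccades(wig)), 0)
  expect_error(synthesize_gaze_trace(150, sampling_rate_hz = 100),
               "250 Hz")
})

test_that("two concatenated saccades are both detected and SRT picks the first", {
  a <- synthesize_gaze_trace(150, noise_sd = 0, duration_ms = 300)
  b <- synthesize_gaze_trace(120, target_side = -1, noise_sd = 0,
                             duration_ms = 300)
  # concatenate on a common uniform clock (a spans -100..300 at 1 kHz)
  b$t_ms <- b$t_ms + 401
  b$x_deg <- b$x_deg + a$x_deg[nrow(a)]
  both <- rbind(a, b)
  ev <- detect_saccades(both)
  expect_equal(nrow(ev), 2)
  expect_equal(extract_srt(ev, 0), ev$onset_ms[1])
  # brute force: minimum over qualifying onsets
  expect_equal(extract_srt(ev, 400), min(ev$onset_ms[ev$onset_ms > 400]) - 400)
  expect_true(is.na(extract_srt(ev, 1000)))
  expect_equal(extract_srt(data.frame(onset_ms = c(90, 200)), 0), 90)
})
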