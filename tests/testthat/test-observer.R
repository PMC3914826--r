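test_that("degenerate SRT sampler is deterministic", {
  obs <- sim_observer(srt_rate_mean = 0.01, srt_rate_sd = 0,
                      srt_express_prob = 0, srt_shift_ms = 50)
  expect_equal(sample_srt(5, obs), rep(150, 5))
})

test_that("single-population sampler matches the analytic reciprocal-normal median", {
  set.seed(11)
  obs <- sim_observer(srt_express_prob = 0)
  x <- sample_srt(10000, obs)
  # median of shift + 1/r with symmetric r: shift + 1/rate_mean
  expect_lt(abs(median(x) - (obs$srt_shift_ms + 1 / obs$srt_rate_mean)), 2)
  expect_true(all(x > obs$srt_shift_ms))
})

test_that("sampled SRT distributions are right-skewed", {
  set.seed(12)
  expect_gt(medcouple(sample_srt(10000, sim_observer(srt_express_prob = 0))), 0)
  expect_gt(medcouple(sample_srt(10000, sim_observer())), 0)
})

test_that("unknown condition labels are rejected", {
  expect_error(simulate_trials(5, "mask", 0.3, sim_observer()), "condition")
  expect_error(generative_p_correct("osm2", 0.3, 150, sim_observer()),
               "condition")
})

test_that("zero mask degradation makes masked trials match the reference at every latency", {
  set.seed(13)
  obs <- sim_observer(mask_degradation = 0, uniform_degradation = 0)
  n <- 20000
  contrast <- psychometric_inverse(0.82, threshold = obs$threshold,
                                   slope = obs$slope, lapse = obs$lapse)
  trials <- do.call(rbind, lapply(saccmask_conditions(), function(cond)
    simulate_trials(n, cond, contrast, obs)))
  # generative p identical across conditions at every SRT
  expect_true(all(abs(trials$sim_p - trials$sim_p[1]) < 1e-12))
  # two-proportion test per occupied 10-ms bin, reference vs each other
  # condition: at alpha = .01 expect close to the nominal false positive
  # rate only
  ref <- trials[trials$condition == "common_offset", ]
  n_tests <- 0L
  n_sig <- 0L
  for (cond in c("osm", "backward", "low_contrast")) {
    d <- trials[trials$condition == cond, ]
    bins <- intersect(floor(ref$srt_ms / 10), floor(d$srt_ms / 10))
    for (b in bins) {
      r <- ref$correct[floor(ref$srt_ms / 10) == b]
      x <- d$correct[floor(d$srt_ms / 10) == b]
      if (length(r) < 10 || length(x) < 10) next
      p <- suppressWarnings(stats::prop.test(c(sum(r), sum(x)),
                                             c(length(r), length(x))))$p.value
      n_tests <- n_tests + 1L
      n_sig <- n_sig + (p < 0.01)
    }
  }
  expect_gt(n_tests, 50)
  expect_lt(n_sig / n_tests, 0.05)
})

test_that("step masking spares fast trials and mixture algebra predicts overall accuracy", {
  set.seed(14)
  obs0 <- sim_observer()
  contrast <- psychometric_inverse(0.82, threshold = obs0$threshold,
                                   slope = obs0$slope, lapse = obs0$lapse)
  # estimate the fast fraction q = P(SRT < mask onset), then choose the
  # degradation d so that 0.82 q + p_slow (1 - q) = 0.60
  q <- mean(sample_srt(200000, obs0) < obs0$mask_onset_ms)
  p_slow <- (0.60 - 0.82 * q) / (1 - q)
  d <- 1 - (p_slow - 0.5) / (0.82 - 0.5)
  obs <- sim_observer(mask_degradation = d)
  tr <- simulate_trials(50000, "osm", contrast, obs)
  expect_lt(abs(mean(tr$correct) - 0.60), 0.01)
  # sparing: fast trials keep the undegraded accuracy
  fast <- tr$srt_ms < obs$mask_onset_ms
  expect_lt(abs(mean(tr$correct[fast]) - 0.82), 0.02)
  expect_lt(abs(mean(tr$correct[!fast]) - p_slow), 0.02)
})

test_that("uniform degradation impairs fast and slow trials alike", {
  set.seed(15)
  obs0 <- sim_observer()
  contrast <- psychometric_inverse(0.82, threshold = obs0$threshold,
                                   slope = obs0$slope, lapse = obs0$lapse)
  # uniform degradation bringing 0.82 down to 0.60 at all latencies
  d_u <- 1 - (0.60 - 0.5) / (0.82 - 0.5)
  obs <- sim_observer(uniform_degradation = d_u)
  tr <- simulate_trials(50000, "low_contrast", contrast, obs)
  expect_lt(abs(mean(tr$correct) - 0.60), 0.01)
  win <- tr$srt_ms >= 120 & tr$srt_ms <= 200
  # accuracy in the fast window stays at the overall level (binomial CI)
  se <- sqrt(0.6 * 0.4 / sum(win))
  expect_lt(abs(mean(tr$correct[win]) - 0.60), 3 * se + 0.005)
})

test_that("experiment layout: trial counts and exact within-block balancing", {
  ex <- simulate_experiment(experiment_config(n_observers = 1, n_blocks = 2,
                                              seed = 42))
  expect_equal(nrow(ex$trials), 2 * 96)
  counts <- table(ex$trials$block, ex$trials$condition)
  expect_true(all(counts == 24))
  expect_error(experiment_config(trials_per_block = 90), "divisible by 4")
})

test_that("simulated experiment holds the staircase accuracy targets and similar medians", {
  fx <- fixture_experiment()
  tr <- analyzable_trials(fx$trials)
  # reference condition is well-specified for the staircase: 0.82 +/- 3pp
  acc <- tapply(tr$correct, tr$condition, mean)
  expect_lt(abs(acc[["common_offset"]] - 0.82), 0.03)
  # low-visibility conditions sit near 0.60 (masked ones may equilibrate
  # slightly above because the staircase model ignores the latency
  # dependence)
  expect_true(all(abs(acc[c("osm", "backward", "low_contrast")] - 0.60) < 0.05))
  # median SRT similar in all four conditions
  med <- tapply(tr$srt_ms, tr$condition, median)
  expect_lt(diff(range(med)), 5)
})
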