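#' Generative model of a simulated saccadic-choice observer
#'
#' Bundles the parameters of the synthetic observer used to generate
#' trial tables with the statistical structure the analysis pipeline
#' assumes: a Weibull psychometric function for contrast sensitivity, a
#' LATER-style (reciprocal-normal) saccadic reaction time sampler with an
#' optional express-saccade component, and a latency-dependent masking
#' impairment.
#'
#' The masking model is a step function of SRT: on `osm` and `backward`
#' trials the probability of a correct response is degraded only when the
#' saccade is initiated at or after `mask_onset_ms`, emulating an
#' impairment that spares responses triggered during early feedforward
#' processing. On `low_contrast` trials an optional degradation applies
#' uniformly at all latencies. Degradation acts multiplicatively on the
#' above-chance component,
#' \deqn{p' = 0.5 + (p - 0.5)(1 - d),}
#' so the 2AFC chance floor of 0.5 can never be crossed. A smooth
#' logistic ramp around `mask_onset_ms` is available via
#' `mask_ramp_ms > 0` for sensitivity analyses (`0` gives the step).
#'
#' @param threshold,slope,guess,lapse Weibull psychometric parameters
#'   (see [psychometric_p_correct()]); `guess` is fixed at 0.5 for 2AFC.
#' @param srt_shift_ms Irreducible latency offset in ms; sampled SRTs
#'   always exceed it.
#' @param srt_rate_mean,srt_rate_sd Mean and SD (1/ms) of the normal rate
#'   distribution of the reciprocal-normal SRT sampler (main population);
#'   the rate is truncated to be positive.
#' @param srt_express_prob Probability that a trial's saccade is drawn
#'   from the express-saccade population, the faster second component of
#'   the bimodal latency distributions described by LATER-type models.
#'   Set to 0 for a single-population sampler.
#' @param srt_express_rate_mean,srt_express_rate_sd Rate parameters
#'   (1/ms) of the express component.
#' @param mask_onset_ms Latency (ms) at and after which masking degrades
#'   accuracy on `osm`/`backward` trials.
#' @param mask_degradation Multiplicative degradation `d` in `[0, 1]`
#'   applied to the above-chance accuracy component for SRT >=
#'   `mask_onset_ms` on masked trials.
#' @param uniform_degradation Degradation in `[0, 1]` applied at all
#'   latencies on `low_contrast` trials. The default 0 reflects that in
#'   the emulated design the low-contrast visibility loss is carried
#'   entirely by the staircase-controlled contrast itself.
#' @param mask_ramp_ms Width (ms) of a logistic transition around
#'   `mask_onset_ms`; 0 (default) gives a hard step.
#' @return An object of class `sim_observer`.
#' @export
#' @examples
#' obs <- sim_observer()
#' obs$mask_onset_ms
sim_observer <- function(threshold = 0.2, slope = 3.5, guess = 0.5,
                         lapse = 0.01, srt_shift_ms = 55,
                         srt_rate_mean = 1 / 150, srt_rate_sd = 0.0019,
                         srt_express_prob = 0.10,
                         srt_express_rate_mean = 1 / 75,
                         srt_express_rate_sd = 0.004,
                         mask_onset_ms = 160, mask_degradation = 0.80,
                         uniform_degradation = 0, mask_ramp_ms = 0) {
  stopifnot(threshold > 0, slope > 0, lapse >= 0, lapse < 0.5,
            srt_shift_ms >= 0, srt_rate_sd >= 0, mask_onset_ms >= 0,
            srt_express_prob >= 0, srt_express_prob <= 1,
            srt_express_rate_mean > 0, srt_express_rate_sd >= 0,
            mask_degradation >= 0, mask_degradation <= 1,
            uniform_degradation >= 0, uniform_degradation <= 1,
            mask_ramp_ms >= 0)
  if (!identical(guess, 0.5)) {
    stop("guess rate is fixed at 0.5 for the 2AFC saccadic choice task")
  }
  if (srt_rate_mean <= 0) {
    stop("srt_rate_mean must be positive")
  }
  structure(list(threshold = threshold, slope = slope, guess = guess,
                 lapse = lapse, srt_shift_ms = srt_shift_ms,
                 srt_rate_mean = srt_rate_mean, srt_rate_sd = srt_rate_sd,
                 srt_express_prob = srt_express_prob,
                 srt_express_rate_mean = srt_express_rate_mean,
                 srt_express_rate_sd = srt_express_rate_sd,
                 mask_onset_ms = mask_onset_ms,
                 mask_degradation = mask_degradation,
                 uniform_degradation = uniform_degradation,
                 mask_ramp_ms = mask_ramp_ms),
            class = "sim_observer")
}

#' @export
print.sim_observer <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulated observer: Weibull(threshold %.3g, slope %.3g), ",
    "SRT ~ %g + 1/N(%.3g, %.3g) ms,\n  mask onset %g ms, ",
    "mask degradation %.2f, uniform degradation %.2f\n"),
    x$threshold, x$slope, x$srt_shift_ms, x$srt_rate_mean, x$srt_rate_sd,
    x$mask_onset_ms, x$mask_degradation, x$uniform_degradation))
  invisible(x)
}

#' Sample saccadic reaction times from a LATER-style model
#'
#' Draws SRTs as `srt_shift_ms + 1/r` with the rate `r` drawn from a
#' normal distribution truncated to positive values, the reciprocal-normal
#' latency distribution implied by linear rise-to-threshold (LATER)
#' models. With probability `srt_express_prob` the rate instead comes
#' from the faster express-saccade component, reproducing the gentle
#' early shoulder of empirical saccadic latency distributions; the
#' mixture is right-skewed with a sharp lower bound.
#'
#' @param n Number of draws.
#' @param observer A [sim_observer()] object (only the `srt_*` fields are
#'   used).
#' @return Numeric vector of SRTs in ms, all strictly greater than
#'   `srt_shift_ms` (unless the rate SDs are 0, in which case draws are
#'   deterministic at `srt_shift_ms + 1/rate_mean`).
#' @export
#' @examples
#' set.seed(1)
#' summary(sample_srt(1000, sim_observer()))
sample_srt <- function(n, observer) {
  stopifnot(inherits(observer, "sim_observer"), n >= 0)
  if (observer$srt_rate_mean <= 0) stop("srt_rate_mean must be positive")
  n <- as.integer(n)
  express <- if (observer$srt_express_prob > 0) {
    stats::runif(n) < observer$srt_express_prob
  } else {
    rep(FALSE, n)
  }
  rate_mean <- ifelse(express, observer$srt_express_rate_mean,
                      observer$srt_rate_mean)
  rate_sd <- ifelse(express, observer$srt_express_rate_sd,
                    observer$srt_rate_sd)
  if (all(rate_sd == 0)) {
    return(observer$srt_shift_ms + 1 / rate_mean)
  }
  r <- stats::rnorm(n, rate_mean, rate_sd)
  bad <- which(r <= 0)
  while (length(bad)) {
    r[bad] <- stats::rnorm(length(bad), rate_mean[bad], rate_sd[bad])
    bad <- bad[r[bad] <= 0]
  }
  observer$srt_shift_ms + 1 / r
}

#' Generative probability of a correct response on a simulated trial
#'
#' Evaluates the observer's psychometric function at the tested contrast
#' and applies the condition- and latency-dependent masking degradation.
#'
#' @param condition Condition label(s), see [saccmask_conditions()].
#' @param contrast Tested contrast(s) in `[0, 1]`.
#' @param srt_ms Saccadic reaction time(s) in ms.
#' @param observer A [sim_observer()] object.
#' @return Vector of probabilities in `[0.5, 1 - lapse]`.
#' @export
generative_p_correct <- function(condition, contrast, srt_ms, observer) {
  stopifnot(inherits(observer, "sim_observer"))
  check_condition(condition)
  p <- psychometric_p_correct(contrast, threshold = observer$threshold,
                              slope = observer$slope, guess = observer$guess,
                              lapse = observer$lapse)
  n <- max(length(condition), length(contrast), length(srt_ms))
  condition <- rep_len(condition, n)
  srt_ms <- rep_len(srt_ms, n)
  p <- rep_len(p, n)
  masked <- condition %in% c("osm", "backward")
  if (observer$mask_ramp_ms > 0) {
    w <- stats::plogis((srt_ms - observer$mask_onset_ms) /
                         (observer$mask_ramp_ms / 4))
  } else {
    w <- as.numeric(srt_ms >= observer$mask_onset_ms)
  }
  d <- numeric(n)
  d[masked] <- observer$mask_degradation * w[masked]
  d[condition == "low_contrast"] <- observer$uniform_degradation
  0.5 + (p - 0.5) * (1 - d)
}

#' Simulate saccadic-choice trials at a fixed contrast
#'
#' Draws `n` trials of a given condition: SRT from [sample_srt()] and
#' correctness from a Bernoulli with probability
#' [generative_p_correct()]. On masked (`osm`, `backward`) trials the
#' impairment applies only to saccades initiated at or after the
#' observer's `mask_onset_ms`; on `low_contrast` trials it applies at all
#' latencies.
#'
#' @param n Number of trials.
#' @param condition A single condition label.
#' @param contrast Tested contrast in `[0, 1]`.
#' @param observer A [sim_observer()] object.
#' @return A data frame with columns `condition`, `contrast`, `srt_ms`,
#'   `correct` (logical) and `sim_p` (the generative probability).
#' @export
#' @examples
#' set.seed(1)
#' head(simulate_trials(5, "osm", 0.25, sim_observer()))
simulate_trials <- function(n, condition, contrast, observer) {
  stopifnot(length(condition) == 1L)
  check_condition(condition)
  srt <- sample_srt(n, observer)
  p <- generative_p_correct(condition, contrast, srt, observer)
  data.frame(condition = rep(condition, n), contrast = rep(contrast, n),
             srt_ms = srt, correct = stats::runif(n) < p, sim_p = p)
}
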