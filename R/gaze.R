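#' Synthesize a gaze trace containing a stereotyped saccade
#'
#' Builds a uniformly sampled horizontal/vertical gaze position trace:
#' fixation at screen centre with Gaussian positional noise, followed by
#' a smooth raised-cosine saccade of the given amplitude starting at
#' `stimulus_onset_ms + srt_ms`. Intended as a constructive fixture for
#' validating [detect_saccades()]; the raised-cosine position profile has
#' near-zero velocity at onset but its acceleration exceeds the standard
#' detection threshold immediately, so detected onsets align with the
#' nominal start to within about one sample.
#'
#' @param srt_ms Saccade onset latency relative to stimulus onset (> 0).
#' @param target_side `+1` (rightward) or `-1` (leftward).
#' @param noise_sd Gaussian positional noise SD in degrees.
#' @param sampling_rate_hz Sampling rate; must be at least 250 Hz to
#'   resolve the saccade.
#' @param duration_ms Total trace duration.
#' @param stimulus_onset_ms Stimulus onset time within the trace.
#' @param amplitude_deg Saccade amplitude in degrees.
#' @param saccade_duration_ms Saccade duration in ms (default 40 ms; the
#'   raised-cosine profile then peaks at
#'   `amplitude_deg * pi / (2 * duration)` deg/s, about 390 deg/s for a
#'   10 degree saccade).
#' @return A data frame of class `gaze_trace` with columns `t_ms`,
#'   `x_deg`, `y_deg` and attributes `stimulus_onset_ms`,
#'   `sampling_rate_hz`.
#' @export
#' @examples
#' tr <- synthesize_gaze_trace(150, noise_sd = 0)
#' detect_saccades(tr)
synthesize_gaze_trace <- function(srt_ms, target_side = 1, noise_sd = 0.02,
                                  sampling_rate_hz = 1000,
                                  duration_ms = 500,
                                  stimulus_onset_ms = 0,
                                  amplitude_deg = 10,
                                  saccade_duration_ms = 40) {
  stopifnot(srt_ms > 0, target_side %in% c(-1, 1), noise_sd >= 0,
            amplitude_deg > 0, saccade_duration_ms > 0)
  if (sampling_rate_hz < 250) {
    stop("sampling rate below 250 Hz cannot resolve the saccade profile")
  }
  dt <- 1000 / sampling_rate_hz
  t_ms <- seq(-100, duration_ms, by = dt)
  onset <- stimulus_onset_ms + srt_ms
  u <- (t_ms - onset) / saccade_duration_ms
  u <- pmin(pmax(u, 0), 1)
  x <- target_side * amplitude_deg * (1 - cos(pi * u)) / 2
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(t_ms), 0, noise_sd)
    y <- stats::rnorm(length(t_ms), 0, noise_sd)
  } else {
    y <- numeric(length(t_ms))
  }
  structure(data.frame(t_ms = t_ms, x_deg = x, y_deg = y),
            stimulus_onset_ms = stimulus_onset_ms,
            sampling_rate_hz = sampling_rate_hz,
            class = c("gaze_trace", "data.frame"))
}

#' Detect saccades in a gaze trace
#'
#' Velocity/acceleration threshold detector with a displacement
#' criterion, mirroring the standard settings of video-based eye-tracker
#' event parsers: an event opens at the first sample where the smoothed
#' velocity exceeds `velocity_thresh` or the absolute acceleration
#' exceeds `accel_thresh`, and closes when both fall back below their
#' thresholds. Events whose total displacement is below `motion_thresh`
#' are discarded as noise. Velocity and acceleration are estimated by
#' central differences after a 3-sample moving-average smoothing of the
#' position signal.
#'
#' @param trace A data frame with columns `t_ms`, `x_deg`, `y_deg`,
#'   uniformly sampled (see [synthesize_gaze_trace()]).
#' @param velocity_thresh Velocity threshold in deg/s (default 30).
#' @param accel_thresh Acceleration threshold in deg/s^2 (default 8000).
#' @param motion_thresh Minimum displacement in deg (default 0.15).
#' @return A data frame with one row per detected saccade: `onset_ms`,
#'   `offset_ms`, `amplitude_deg`, `peak_velocity_deg_s`, `direction`
#'   (`"left"`/`"right"`), sorted by onset. Zero rows if none.
#' @export
detect_saccades <- function(trace, velocity_thresh = 30,
                            accel_thresh = 8000, motion_thresh = 0.15) {
  stopifnot(all(c("t_ms", "x_deg", "y_deg") %in% names(trace)))
  t <- trace$t_ms
  if (length(t) < 3L) stop("gaze trace must contain at least 3 samples")
  dts <- diff(t)
  if (diff(range(dts)) > 1e-6 * mean(dts) + 1e-9) {
    stop("gaze trace must be uniformly sampled")
  }
  dt_s <- mean(dts) / 1000
  smooth3 <- function(v) {
    s <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    s[1L] <- v[1L]
    s[length(v)] <- v[length(v)]
    as.numeric(s)
  }
  x <- smooth3(trace$x_deg)
  y <- smooth3(trace$y_deg)
  cdiff <- function(v) {
    n <- length(v)
    d <- c(v[2L] - v[1L], (v[3:n] - v[1:(n - 2L)]) / 2, v[n] - v[n - 1L])
    d / dt_s
  }
  vx <- cdiff(x)
  vy <- cdiff(y)
  speed <- sqrt(vx^2 + vy^2)
  accel <- cdiff(speed)
  active <- speed > velocity_thresh | abs(accel) > accel_thresh
  if (!any(active)) {
    return(empty_saccade_table())
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  events <- lapply(keep, function(k) {
    i0 <- starts[k]
    i1 <- ends[k]
    disp <- sqrt((x[i1] - x[i0])^2 + (y[i1] - y[i0])^2)
    if (disp < motion_thresh) return(NULL)
    data.frame(onset_ms = t[i0], offset_ms = t[i1], amplitude_deg = disp,
               peak_velocity_deg_s = max(speed[i0:i1]),
               direction = if (x[i1] >= x[i0]) "right" else "left")
  })
  events <- events[!vapply(events, is.null, logical(1))]
  if (!length(events)) {
    return(empty_saccade_table())
  }
  out <- do.call(rbind, events)
  out[order(out$onset_ms), , drop = FALSE]
}

empty_saccade_table <- function() {
  data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
             amplitude_deg = numeric(0), peak_velocity_deg_s = numeric(0),
             direction = character(0))
}

#' Saccadic reaction time from detected saccade events
#'
#' The SRT is the onset of the first saccade after stimulus onset.
#'
#' @param events Saccade table from [detect_saccades()] (sorted by onset).
#' @param stimulus_onset_ms Stimulus onset time (same clock as the events).
#' @return SRT in ms relative to stimulus onset, or `NA` if no saccade
#'   follows stimulus onset.
#' @export
#' @examples
#' ev <- data.frame(onset_ms = c(90, 200))
#' extract_srt(ev, 0)  # 90
extract_srt <- function(events, stimulus_onset_ms = 0) {
  after <- events$onset_ms[events$onset_ms > stimulus_onset_ms]
  if (!length(after)) return(NA_real_)
  min(after) - stimulus_onset_ms
}
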