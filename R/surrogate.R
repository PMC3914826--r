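#' One accuracy-matched surrogate draw
#'
#' Builds a pseudo-condition embodying the null hypothesis that a
#' visibility impairment is independent of response time: SRTs are drawn
#' (with replacement) from the *correct* trials of a high-visibility
#' source condition, and a uniformly random subset of them is relabelled
#' "incorrect" so that the realized proportion correct matches the
#' target condition's accuracy exactly (to the nearest achievable count,
#' `round(n_trials * (1 - target_accuracy))` relabels, round-half-up).
#' Because the relabelling ignores SRT, any latency dependence of the
#' real impairment shows up as a deviation from the surrogate ensemble.
#'
#' @param source_correct_srt_ms SRTs of the source condition's correct
#'   trials.
#' @param n_trials Number of trials to draw.
#' @param target_accuracy Proportion correct to match, in `(0, 1]`.
#' @return Data frame with columns `srt_ms` and `correct`.
#' @export
#' @examples
#' set.seed(1)
#' d <- make_surrogate_draw(runif(500, 100, 300), 100, 0.6)
#' mean(d$correct)  # exactly 0.6
make_surrogate_draw <- function(source_correct_srt_ms, n_trials,
                                target_accuracy) {
  if (target_accuracy <= 0 || target_accuracy > 1) {
    stop("target_accuracy must lie in (0, 1]")
  }
  stopifnot(n_trials >= 1, length(source_correct_srt_ms) >= 1)
  srt <- sample(source_correct_srt_ms, n_trials, replace = TRUE)
  n_relabel <- round_half_up(n_trials * (1 - target_accuracy))
  correct <- rep(TRUE, n_trials)
  if (n_relabel > 0) {
    correct[sample.int(n_trials, n_relabel)] <- FALSE
  }
  data.frame(srt_ms = srt, correct = correct)
}

#' Ensemble of accuracy-matched surrogate draws
#'
#' Repeats [make_surrogate_draw()] `n_draws` times and records, for each
#' draw, the minimum SRT ([minimum_srt()]) and optionally the cumulative
#' accuracy time-course evaluated on a common time grid. The ensemble's
#' minimum-SRT distribution and time-course band quantify what the
#' observed statistics would look like if the impairment were uniform
#' over time.
#'
#' @param source_trials Analyzable trials of the source (high-visibility)
#'   condition: data frame with `srt_ms` and `correct`.
#' @param target_trials Analyzable trials of the target (low-visibility)
#'   condition; sets the draw size and the accuracy to match.
#' @param n_draws Number of surrogate draws (default 500).
#' @param width_ms,k,alpha,yates Minimum-SRT settings (see
#'   [minimum_srt()]).
#' @param timecourse_grid Optional numeric vector of times (ms) at which
#'   each draw's cumulative accuracy is evaluated (typically the observed
#'   condition's sorted SRTs at or above the display threshold). `NULL`
#'   skips the time-course computation.
#' @return An object of class `surrogate_ensemble`: list with
#'   `min_srt_distribution` (length `n_draws`, `NA` where undefined),
#'   `n_undefined`, `target_accuracy`, `n_trials`, `timecourse_grid` and
#'   `timecourse_draws` (draws x grid matrix, or `NULL`).
#' @export
surrogate_ensemble <- function(source_trials, target_trials,
                               n_draws = 500, width_ms = 10, k = 5,
                               alpha = 0.05, yates = FALSE,
                               timecourse_grid = NULL) {
  stopifnot(all(c("srt_ms", "correct") %in% names(source_trials)),
            all(c("srt_ms", "correct") %in% names(target_trials)),
            n_draws >= 2)
  src <- source_trials$srt_ms[source_trials$correct]
  if (!length(src)) stop("source condition has no correct trials")
  n_trials <- nrow(target_trials)
  target_accuracy <- mean(target_trials$correct)
  mins <- numeric(n_draws)
  tc <- if (!is.null(timecourse_grid)) {
    matrix(NA_real_, n_draws, length(timecourse_grid))
  }
  for (b in seq_len(n_draws)) {
    d <- make_surrogate_draw(src, n_trials, target_accuracy)
    stopifnot(abs(mean(d$correct) - target_accuracy) < 1 / n_trials)
    mins[b] <- minimum_srt(bin_srt(d$srt_ms, d$correct, width_ms),
                           k = k, alpha = alpha, yates = yates)$min_srt_ms
    if (!is.null(timecourse_grid)) {
      tc[b, ] <- cum_accuracy_at(d$srt_ms, d$correct, timecourse_grid)
    }
  }
  structure(list(min_srt_distribution = mins,
                 n_undefined = sum(is.na(mins)),
                 n_draws = n_draws, n_trials = n_trials,
                 target_accuracy = target_accuracy,
                 timecourse_grid = timecourse_grid,
                 timecourse_draws = tc),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(paste0(
    "Surrogate ensemble: %d draws of %d trials at accuracy %.3f; ",
    "%d draws with undefined minimum SRT\n"),
    x$n_draws, x$n_trials, x$target_accuracy, x$n_undefined))
  invisible(x)
}

#' Compare an observed minimum SRT against the surrogate interval
#'
#' Percentile interval (order statistics) of the surrogate minimum-SRT
#' distribution, and a classification of the observed minimum SRT as
#' `"escaping"` (below the lower bound: faster than a time-uniform
#' impairment allows), `"consistent"` (inside) or `"slower"` (above the
#' upper bound). An undefined minimum SRT — no run of significant bins
#' anywhere — is the slowest possible outcome, so undefined values
#' (observed or surrogate) are ordered as `+Inf`: draws with undefined
#' minima are counted into the upper tail (the upper bound becomes `Inf`
#' once more than `(1 - level)/2` of the draws are undefined), and an
#' undefined observed minimum is `"consistent"` exactly when the
#' ensemble itself produces undefined minima at a compatible rate.
#'
#' @param ensemble A [surrogate_ensemble()] object.
#' @param observed_min_srt_ms Observed minimum SRT (ms) of the target
#'   condition, or `NA` if undefined.
#' @param level Confidence level (default 0.95).
#' @return List of class `surrogate_min_srt_ci`: `lower`, `upper`
#'   (possibly `Inf`), `flag`, `n_undefined`, `unreliable` (`TRUE` with
#'   a warning when more than half the draws had undefined minimum SRT).
#' @export
surrogate_min_srt_ci <- function(ensemble, observed_min_srt_ms,
                                 level = 0.95) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  mins <- ensemble$min_srt_distribution
  unreliable <- ensemble$n_undefined > ensemble$n_draws / 2
  if (unreliable) {
    warning("more than half of the surrogate draws had an undefined ",
            "minimum SRT; the interval is unreliable")
  }
  ordered <- mins
  ordered[is.na(ordered)] <- Inf
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- stats::quantile(ordered, probs, type = 1, names = FALSE)
  obs <- if (is.na(observed_min_srt_ms)) Inf else observed_min_srt_ms
  flag <- if (obs < ci[1L]) {
    "escaping"
  } else if (obs > ci[2L]) {
    "slower"
  } else {
    "consistent"
  }
  structure(list(lower = ci[1L], upper = ci[2L], level = level,
                 flag = flag, observed = observed_min_srt_ms,
                 n_undefined = ensemble$n_undefined,
                 unreliable = unreliable),
            class = "surrogate_min_srt_ci")
}

#' @export
print.surrogate_min_srt_ci <- function(x, ...) {
  cat(sprintf(
    "Observed minimum SRT %s vs surrogate %.0f%% CI [%s, %s]: %s\n",
    if (is.na(x$observed)) "undefined" else paste0(x$observed, " ms"),
    100 * x$level, x$lower, x$upper, x$flag))
  invisible(x)
}

#' Time points where an observed accuracy time-course leaves the
#' surrogate band
#'
#' At each grid point, the observed cumulative accuracy is compared with
#' the surrogate ensemble's empirical `1 - alpha` percentile band
#' (non-parametric bootstrap test, pointwise — no correction across time
#' points). Contiguous significant runs are reported as intervals.
#'
#' @param observed An [accuracy_timecourse()] of the target condition.
#' @param ensemble A [surrogate_ensemble()] built with
#'   `timecourse_grid` equal to the displayed observed time points.
#' @param alpha Pointwise significance level (default 0.05).
#' @return List with `time_ms`, `significant` (logical per grid point),
#'   `band_lower`, `band_upper`, and `intervals` (data frame of
#'   contiguous significant runs: `start_ms`, `end_ms`).
#' @export
timecourse_comparison <- function(observed, ensemble, alpha = 0.05) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  if (is.null(ensemble$timecourse_draws)) {
    stop("ensemble was built without a time-course grid")
  }
  grid <- ensemble$timecourse_grid
  obs_t <- observed$time_ms[observed$display]
  obs_a <- observed$cum_accuracy[observed$display]
  if (length(obs_t) != length(grid) || any(abs(obs_t - grid) > 1e-9)) {
    stop("internal error: observed time points do not match the ",
         "ensemble's grid")
  }
  band <- apply(ensemble$timecourse_draws, 2L, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                type = 1)
  sig <- obs_a < band[1L, ] | obs_a > band[2L, ]
  sig[is.na(sig)] <- FALSE
  intervals <- if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(start_ms = grid[starts[keep]], end_ms = grid[ends[keep]])
  } else {
    data.frame(start_ms = numeric(0), end_ms = numeric(0))
  }
  list(time_ms = grid, significant = sig, band_lower = band[1L, ],
       band_upper = band[2L, ], intervals = intervals)
}
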