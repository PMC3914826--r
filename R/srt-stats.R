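#' Bin saccadic reaction times into fixed-width bins
#'
#' Half-open bins `[left, left + width)` anchored at 0 ms: a trial with
#' SRT `t` falls in the bin with left edge `floor(t / width) * width`.
#' Anchoring is stated explicitly because the minimum-SRT estimate shifts
#' with the anchor.
#'
#' @param srt_ms Numeric SRTs of analyzable trials (ms).
#' @param correct Logical correctness vector of the same length.
#' @param width_ms Bin width in ms (default 10).
#' @return A data frame of class `binned_srt` with columns `bin_left`
#'   (all left edges from 0 to the maximum occupied bin), `n_correct`,
#'   `n_incorrect`; attribute `width_ms`.
#' @export
#' @examples
#' b <- bin_srt(c(119.9, 120, 125), c(TRUE, FALSE, TRUE))
#' b[b$bin_left >= 110, ]
bin_srt <- function(srt_ms, correct, width_ms = 10) {
  if (width_ms <= 0) stop("bin width must be positive")
  stopifnot(length(srt_ms) == length(correct))
  if (length(srt_ms) == 0L) {
    out <- data.frame(bin_left = numeric(0), n_correct = integer(0),
                      n_incorrect = integer(0))
    return(structure(out, width_ms = width_ms,
                     class = c("binned_srt", "data.frame")))
  }
  stopifnot(all(is.finite(srt_ms)), all(srt_ms >= 0))
  idx <- floor(srt_ms / width_ms) + 1L  # 1-based bin index from 0 ms
  nbins <- max(idx)
  n_correct <- tabulate(idx[correct], nbins)
  n_incorrect <- tabulate(idx[!correct], nbins)
  out <- data.frame(bin_left = (seq_len(nbins) - 1L) * width_ms,
                    n_correct = n_correct, n_incorrect = n_incorrect)
  structure(out, width_ms = width_ms, class = c("binned_srt", "data.frame"))
}

#' Per-bin chi-square test for an excess of correct responses
#'
#' One-sample chi-square against the 50/50 null with 1 degree of
#' freedom, \eqn{\chi^2 = (n_c - n_i)^2 / (n_c + n_i)}, by default
#' without continuity correction. A bin counts as significant only if
#' the statistic reaches the critical value *and* correct responses
#' outnumber errors (directional gate): a bin dominated by errors must
#' never count toward the minimum SRT. Empty bins are never significant.
#'
#' @param n_correct,n_incorrect Non-negative counts (vectorised).
#' @param alpha Significance level (default 0.05).
#' @param yates Apply Yates' continuity correction
#'   (\eqn{(|n_c - n_i| - 1)^2 / n}); default `FALSE`.
#' @return Logical vector: significant excess of correct responses.
#' @export
#' @examples
#' chi2_bin_test(9, 1)   # chi2 = 6.4 >= 3.841 -> TRUE
#' chi2_bin_test(5, 5)   # chi2 = 0 -> FALSE
#' chi2_bin_test(1, 9)   # significant, but errors dominate -> FALSE
chi2_bin_test <- function(n_correct, n_incorrect, alpha = 0.05,
                          yates = FALSE) {
  stopifnot(all(n_correct >= 0), all(n_incorrect >= 0), alpha > 0,
            alpha < 1)
  n <- n_correct + n_incorrect
  d <- abs(n_correct - n_incorrect)
  if (yates) d <- pmax(d - 1, 0)
  chi2 <- ifelse(n > 0, d^2 / n, 0)
  crit <- stats::qchisq(1 - alpha, df = 1)
  chi2 >= crit & n_correct > n_incorrect
}

#' Minimum saccadic reaction time from binned counts
#'
#' The minimum SRT is the left edge of the first 10-ms bin that begins a
#' run of at least `k` consecutive bins in which correct responses
#' significantly outnumber errors ([chi2_bin_test()]). It estimates the
#' earliest time at which stimulus information drives selective
#' behaviour. When no qualifying run exists the minimum SRT is undefined
#' and `NA` is returned — a first-class result, not an error, since
#' surrogate resamples can legitimately produce it.
#'
#' @param binned A [bin_srt()] result.
#' @param k Required run length (default 5 consecutive bins).
#' @param alpha Per-bin significance level.
#' @param yates Passed to [chi2_bin_test()].
#' @param run_rule `"starts_at"` (default): the reported bin is the first
#'   bin of the run. `"contains"`: the first significant bin belonging to
#'   any window of `k` consecutive significant bins (identical result;
#'   kept as an explicit flag for the alternative reading in which the
#'   run may merely contain the reported bin).
#' @return A list of class `min_srt_result` with `min_srt_ms` (left edge
#'   in ms, or `NA`), `significant` (per-bin logical), `k`, `alpha`.
#' @export
#' @examples
#' b <- bin_srt(rep(seq(125, 165, 10), each = 10), rep(TRUE, 50))
#' minimum_srt(b)$min_srt_ms  # 120
minimum_srt <- function(binned, k = 5, alpha = 0.05, yates = FALSE,
                        run_rule = c("starts_at", "contains")) {
  if (k < 1) stop("run length k must be at least 1")
  run_rule <- match.arg(run_rule)
  stopifnot(inherits(binned, "binned_srt") || all(
    c("bin_left", "n_correct", "n_incorrect") %in% names(binned)))
  sig <- chi2_bin_test(binned$n_correct, binned$n_incorrect,
                       alpha = alpha, yates = yates)
  nb <- length(sig)
  min_srt <- NA_real_
  if (nb >= k) {
    # rolling count of significant bins in windows of length k
    run <- stats::filter(as.numeric(sig), rep(1, k), sides = 1)
    start <- which(run == k)
    if (length(start)) min_srt <- binned$bin_left[start[1L] - k + 1L]
  }
  structure(list(min_srt_ms = min_srt, significant = sig, k = k,
                 alpha = alpha), class = "min_srt_result")
}

#' @export
print.min_srt_result <- function(x, ...) {
  cat(sprintf("Minimum SRT: %s (k = %d consecutive bins, alpha = %g)\n",
              if (is.na(x$min_srt_ms)) "undefined" else
                paste0(x$min_srt_ms, " ms"), x$k, x$alpha))
  invisible(x)
}

#' Minimum SRT per observer, and averaged across observers
#'
#' Computes [minimum_srt()] on each observer's trials of one condition
#' and averages the defined per-observer values, alongside the pooled
#' (all observers together) estimate used for time-course analyses.
#'
#' @param trials Analyzable trial data frame with `observer`, `srt_ms`,
#'   `correct` columns (one condition).
#' @param width_ms,k,alpha,yates Passed to [bin_srt()]/[minimum_srt()].
#' @return List with `per_observer` (named numeric, `NA` where
#'   undefined), `mean_across_observers`, and `pooled`.
#' @export
min_srt_by_observer <- function(trials, width_ms = 10, k = 5,
                                alpha = 0.05, yates = FALSE) {
  stopifnot(all(c("observer", "srt_ms", "correct") %in% names(trials)))
  per <- vapply(split(trials, trials$observer), function(d) {
    minimum_srt(bin_srt(d$srt_ms, d$correct, width_ms), k = k,
                alpha = alpha, yates = yates)$min_srt_ms
  }, numeric(1))
  pooled <- minimum_srt(bin_srt(trials$srt_ms, trials$correct, width_ms),
                        k = k, alpha = alpha, yates = yates)$min_srt_ms
  list(per_observer = per,
       mean_across_observers = mean(per, na.rm = TRUE),
       pooled = pooled)
}

#' Cumulative accuracy time-course
#'
#' At each time point `t` of the time-ordered single-trial SRTs, the
#' accumulated accuracy is the proportion of correct responses among all
#' trials with SRT <= `t`; e.g. the value at 200 ms is the proportion
#' correct of all saccades initiated within 200 ms. The first time
#' points average very few trials, so points before `display_min_ms` are
#' computed but flagged not-for-display.
#'
#' @param trials Data frame with `srt_ms` and `correct` columns, or the
#'   two vectors via `srt_ms`/`correct` arguments.
#' @param display_min_ms Earliest latency shown by default (110 ms).
#' @return A data frame of class `accuracy_timecourse` with columns
#'   `time_ms` (sorted SRTs), `cum_accuracy`, `n_cum` (trials entering
#'   the estimate) and `display` (logical).
#' @export
#' @examples
#' tc <- accuracy_timecourse(data.frame(srt_ms = c(100, 150, 200),
#'                                      correct = c(TRUE, FALSE, TRUE)))
#' tc$cum_accuracy  # 1, 1/2, 2/3
accuracy_timecourse <- function(trials, display_min_ms = 110) {
  stopifnot(all(c("srt_ms", "correct") %in% names(trials)))
  if (nrow(trials) == 0L) stop("cannot compute a time-course of no trials")
  o <- order(trials$srt_ms)
  t <- trials$srt_ms[o]
  cum <- cumsum(trials$correct[o]) / seq_along(t)
  structure(data.frame(time_ms = t, cum_accuracy = cum,
                       n_cum = seq_along(t),
                       display = t >= display_min_ms),
            display_min_ms = display_min_ms,
            class = c("accuracy_timecourse", "data.frame"))
}

# internal: cumulative accuracy of (srt, correct) evaluated at grid times
cum_accuracy_at <- function(srt_ms, correct, grid) {
  o <- order(srt_ms)
  t <- srt_ms[o]
  cs <- cumsum(correct[o])
  idx <- findInterval(grid, t)
  ifelse(idx > 0, cs[pmax(idx, 1L)] / idx, NA_real_)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (trials) with replacement `n_boot` times, applies
#' `statistic_fn`, and returns the percentile interval of the resampled
#' statistics. Resamples on which the statistic is undefined (`NA`) are
#' counted and reported, not silently dropped.
#'
#' @param statistic_fn Function of a data frame (or vector) returning a
#'   single number, possibly `NA`.
#' @param data A data frame (rows resampled) or an atomic vector.
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param level Confidence level (default 0.95).
#' @return List of class `bootstrap_ci`: `lower`, `upper`, `level`,
#'   `n_boot`, `n_undefined`, `boot_stats`.
#' @export
#' @examples
#' set.seed(1)
#' bootstrap_ci(mean, rnorm(100), n_boot = 200)[c("lower", "upper")]
bootstrap_ci <- function(statistic_fn, data, n_boot = 500, level = 0.95,
                         ...) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  stopifnot(level > 0, level < 1)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  stats_out <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    resample <- if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
    as.numeric(statistic_fn(resample, ...))
  }, numeric(1))
  defined <- stats_out[!is.na(stats_out)]
  n_undef <- n_boot - length(defined)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- if (length(defined)) {
    stats::quantile(defined, probs, type = 8, names = FALSE)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(lower = ci[1L], upper = ci[2L], level = level,
                 n_boot = n_boot, n_undefined = n_undef,
                 boot_stats = stats_out), class = "bootstrap_ci")
}

#' Median saccadic reaction time
#'
#' Standard sample median (midpoint convention for even n).
#'
#' @param srt_ms Numeric vector of analyzable SRTs.
#' @return Median in ms.
#' @export
median_srt <- function(srt_ms) {
  srt_ms <- srt_ms[is.finite(srt_ms)]
  if (!length(srt_ms)) stop("cannot take the median of no SRTs")
  stats::median(srt_ms)
}

#' Effective mask duration implied by a minimum SRT
#'
#' A saccade initiated at the minimum SRT reflects stimulus processing
#' that excludes the afferent visual delay and the saccadic motor
#' initiation time, together about 90 ms. The difference bounds the
#' effective duration for which the mask could have acted on the
#' decision-relevant processing: e.g. a 125 ms minimum SRT implies an
#' effective mask exposure of at most 35 ms.
#'
#' @param min_srt_ms Minimum SRT in ms.
#' @param overhead_ms Afferent-plus-motor overhead in ms (default 90).
#' @return Effective mask duration bound in ms.
#' @export
#' @examples
#' effective_mask_duration(125)  # 35
effective_mask_duration <- function(min_srt_ms, overhead_ms = 90) {
  min_srt_ms - overhead_ms
}
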