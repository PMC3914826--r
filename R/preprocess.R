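#' Medcouple robust skewness estimator
#'
#' The medcouple of a sample is the median of the kernel
#' \deqn{h(x_i, x_j) = \frac{(x_j - m) - (m - x_i)}{x_j - x_i}}
#' over all pairs with \eqn{x_i \le m \le x_j}, where \eqn{m} is the
#' sample median; observations tied with the median use the standard
#' sign-pattern special-case kernel. The result is a bounded, robust
#' skewness measure in `[-1, 1]` (0 for symmetric samples, positive for
#' right skew), invariant to location shifts and positive scalings.
#'
#' This is the plain O(n^2) evaluation of the definition, adequate for
#' the per-cell reaction-time samples this package screens (thousands of
#' trials at most).
#'
#' @param x Numeric sample with at least 3 finite values.
#' @return The medcouple, a scalar in `[-1, 1]`.
#' @references Brys, Hubert and Struyf (2004), A robust measure of
#'   skewness. Journal of Computational and Graphical Statistics 13(4).
#' @export
#' @examples
#' medcouple(c(1, 2, 3))            # 0: symmetric
#' medcouple(rexp(100))             # > 0: right-skewed
medcouple <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("medcouple requires at least 3 finite observations")
  x <- sort(x)
  m <- stats::median(x)
  xl <- x[x <= m]
  xr <- x[x >= m]
  # regular kernel for pairs not both equal to the median
  h <- outer(xr - m, m - xl, function(a, b) (a - b) / (a + b))
  k <- sum(x == m)
  if (k > 0L) {
    # pairs of median-tied points: sign pattern making ties symmetric
    nl <- length(xl)
    ir <- seq_len(k)                 # tied points lead xr
    il <- nl - k + seq_len(k)        # tied points trail xl
    special <- outer(ir, seq_len(k), function(i, j) sign(i + j - 1L - k))
    h[ir, il] <- special
  }
  stats::median(h)
}

#' Adjusted boxplot fences for skewed samples
#'
#' Outlier fences that widen Tukey's 1.5 IQR rule asymmetrically
#' according to the medcouple MC:
#' for MC >= 0 the fences are
#' `[Q1 - 1.5 exp(-4 MC) IQR, Q3 + 1.5 exp(3 MC) IQR]`,
#' and for MC < 0 the exponents swap to
#' `[Q1 - 1.5 exp(-3 MC) IQR, Q3 + 1.5 exp(4 MC) IQR]`.
#' With MC = 0 this reduces to the classical Tukey fences. Quartiles use
#' the median-unbiased quantile convention (`type = 8`), stated
#' explicitly because fence values depend on it.
#'
#' @param x Numeric sample with at least 4 finite values.
#' @return Named numeric vector `c(lower, upper)`. When the IQR is zero
#'   a degenerate-sample warning is issued and the fences collapse to
#'   `[Q1, Q3]`.
#' @references Hubert and Vandervieren (2008), An adjusted boxplot for
#'   skewed distributions. Computational Statistics & Data Analysis 52.
#' @export
adjusted_boxplot_fences <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("adjusted boxplot fences require n >= 4")
  q <- stats::quantile(x, c(0.25, 0.75), type = 8, names = FALSE)
  iqr <- q[2L] - q[1L]
  if (iqr == 0) {
    warning("degenerate sample: zero IQR, fences collapse to [Q1, Q3]")
    return(c(lower = q[1L], upper = q[2L]))
  }
  mc <- medcouple(x)
  if (mc >= 0) {
    c(lower = q[1L] - 1.5 * exp(-4 * mc) * iqr,
      upper = q[2L] + 1.5 * exp(3 * mc) * iqr)
  } else {
    c(lower = q[1L] - 1.5 * exp(-3 * mc) * iqr,
      upper = q[2L] + 1.5 * exp(4 * mc) * iqr)
  }
}

#' Flag anticipatory (fast-outlier) trials
#'
#' Trials with SRT strictly faster than the cutoff are flagged as
#' anticipations; an SRT exactly at the cutoff is retained.
#'
#' @param trials Trial data frame with an `srt_ms` column.
#' @param cutoff_ms Anticipation cutoff in ms (default 70).
#' @return `trials` with a logical `excluded_fast` column.
#' @export
flag_fast_outliers <- function(trials, cutoff_ms = 70) {
  stopifnot("srt_ms" %in% names(trials))
  trials$excluded_fast <- trials$srt_ms < cutoff_ms
  trials
}

#' Flag slow-outlier trials with adjusted boxplot fences
#'
#' Within each grouping cell (by default observer x condition, since SRT
#' distributions differ across observers), computes
#' [adjusted_boxplot_fences()] on the fast-outlier-free SRTs and flags
#' trials above the upper fence. Only the upper fence is used: the lower
#' tail is already handled by the anticipation cutoff.
#'
#' @param trials Trial data frame with `srt_ms` and an `excluded_fast`
#'   column (see [flag_fast_outliers()]).
#' @param by Character vector of grouping columns.
#' @return `trials` with a logical `excluded_slow` column (always `FALSE`
#'   for trials already flagged fast).
#' @export
flag_slow_outliers <- function(trials, by = c("observer", "condition")) {
  stopifnot(all(c("srt_ms", "excluded_fast") %in% names(trials)),
            all(by %in% names(trials)))
  trials$excluded_slow <- FALSE
  cells <- interaction(trials[by], drop = TRUE)
  for (cell in levels(cells)) {
    in_cell <- cells == cell & !trials$excluded_fast
    if (sum(in_cell) < 4L) next
    fences <- adjusted_boxplot_fences(trials$srt_ms[in_cell])
    trials$excluded_slow[in_cell] <- trials$srt_ms[in_cell] > fences["upper"]
  }
  trials
}

#' Flag trials collected before staircase stabilisation
#'
#' Within each observer x condition cell, marks the trials that occurred
#' before the first trial at which the corresponding QUEST staircase had
#' arrived at a stable threshold estimate (see [quest_first_stable()]).
#'
#' @param trials Trial data frame with `observer` and `condition`
#'   columns, in chronological order within each cell.
#' @param staircases Nested list `staircases[[observer]][[condition]]` of
#'   `quest_state` objects, as returned by [simulate_experiment()].
#' @param window,tolerance Stability rule (see [quest_stable()]).
#' @return `trials` with a logical `excluded_unstable` column. If a
#'   staircase never stabilised, all trials of its cell are flagged and
#'   a warning is issued.
#' @export
select_stable_trials <- function(trials, staircases, window = 40,
                                 tolerance = 0.12) {
  stopifnot(all(c("observer", "condition") %in% names(trials)))
  trials$excluded_unstable <- FALSE
  for (obs in unique(trials$observer)) {
    for (cond in unique(trials$condition[trials$observer == obs])) {
      q <- staircases[[obs]][[cond]]
      if (is.null(q)) {
        stop("missing staircase history for observer '", obs,
             "', condition '", cond, "'")
      }
      idx <- which(trials$observer == obs & trials$condition == cond)
      fs <- quest_first_stable(q, window = window, tolerance = tolerance)
      if (is.na(fs)) {
        warning("staircase for observer '", obs, "', condition '", cond,
                "' never stabilised; all its trials excluded")
        trials$excluded_unstable[idx] <- TRUE
      } else if (fs > 1L) {
        trials$excluded_unstable[idx[seq_len(min(fs - 1L, length(idx)))]] <- TRUE
      }
    }
  }
  trials
}

#' Preprocess a trial table into the analyzable trial set
#'
#' Applies the exclusion cascade in a fixed order: anticipations (SRT
#' faster than `fast_cutoff_ms`), then slow outliers (adjusted boxplot
#' upper fence on the anticipation-free SRTs, per grouping cell), then
#' staircase-stability selection when histories are supplied. The flagged
#' set does not depend on the row order of the input.
#'
#' @param trials Trial data frame (`observer`, `condition`, `srt_ms`, ...).
#' @param staircases Optional nested staircase list for stability
#'   selection (see [select_stable_trials()]).
#' @param fast_cutoff_ms Anticipation cutoff (ms).
#' @param by Grouping columns for the slow-outlier fences.
#' @param window,tolerance Staircase stability rule.
#' @param verbose Print per-cell exclusion counts.
#' @return `trials` with logical columns `excluded_fast`, `excluded_slow`,
#'   `excluded_unstable` and `analyzable` (the conjunction of none set).
#' @export
preprocess_trials <- function(trials, staircases = NULL,
                              fast_cutoff_ms = 70,
                              by = c("observer", "condition"),
                              window = 40, tolerance = 0.12,
                              verbose = FALSE) {
  trials <- flag_fast_outliers(trials, cutoff_ms = fast_cutoff_ms)
  trials <- flag_slow_outliers(trials, by = by)
  if (!is.null(staircases)) {
    trials <- select_stable_trials(trials, staircases, window = window,
                                   tolerance = tolerance)
  } else {
    trials$excluded_unstable <- FALSE
  }
  trials$analyzable <- !(trials$excluded_fast | trials$excluded_slow |
                           trials$excluded_unstable)
  if (verbose) {
    tab <- stats::aggregate(cbind(n = !trials$analyzable) ~
                              trials$observer + trials$condition, FUN = sum)
    message(sprintf("retained %d / %d trials (%.1f%%)",
                    sum(trials$analyzable), nrow(trials),
                    100 * mean(trials$analyzable)))
  }
  trials
}

#' Keep only analyzable trials
#'
#' @param trials Output of [preprocess_trials()].
#' @return The subset of rows with `analyzable == TRUE`.
#' @export
analyzable_trials <- function(trials) {
  stopifnot("analyzable" %in% names(trials))
  trials[trials$analyzable, , drop = FALSE]
}

required_trial_columns <- c("observer", "condition", "block", "trial",
                            "contrast", "srt_ms", "correct")

#' Read a trial table from CSV
#'
#' Reads the shared per-trial CSV schema
#' (`observer,condition,block,trial,contrast,srt_ms,correct`, plus any
#' optional `sim_`-prefixed ground-truth columns). Header matching is
#' case-insensitive, and `column_map` renames nonstandard headers, e.g.
#' `column_map = c(srt_ms = "RT", correct = "hit")`.
#'
#' @param path Path to the CSV file.
#' @param column_map Optional named character vector mapping standard
#'   column names to the file's actual headers.
#' @return A trial data frame with `correct` coerced to logical.
#' @export
read_trials <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("trial table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- tolower(column_map[[std]])
      if (src %in% names(df)) names(df)[names(df) == src] <- std
    }
  }
  missing <- setdiff(required_trial_columns, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.logical(df$correct)) {
    if (is.numeric(df$correct)) {
      df$correct <- df$correct != 0
    } else {
      df$correct <- tolower(as.character(df$correct)) %in%
        c("true", "t", "1", "yes")
    }
  }
  bad <- which(!is.finite(df$srt_ms) | df$srt_ms <= 0)
  if (length(bad)) {
    stop("unparseable srt_ms in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  df
}

#' Write a trial table to CSV
#'
#' Round-trips with [read_trials()].
#'
#' @param trials Trial data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
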