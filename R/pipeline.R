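#' Analyze a preprocessed trial table
#'
#' Runs the full descriptive and inferential battery on the analyzable
#' trials: per-condition accuracy, median SRT, minimum SRT (pooled and
#' per observer), accuracy-matched surrogate intervals for every
#' low-visibility condition against the high-visibility source, optional
#' time-course comparisons, and the condition-level ANOVAs.
#'
#' @param trials Preprocessed trial data frame (see
#'   [preprocess_trials()]); only rows with `analyzable == TRUE` are
#'   used. Must contain the source condition and at least one target.
#' @param source_condition High-visibility reference condition for the
#'   surrogate null (default `"common_offset"`).
#' @param n_draws Surrogate draws per condition (default 500).
#' @param width_ms,k,alpha Minimum-SRT settings.
#' @param timecourse Also run the pointwise surrogate band comparison of
#'   the cumulative accuracy time-course (slower; default `FALSE`).
#' @param display_min_ms Earliest latency entering the time-course
#'   comparison.
#' @return List of class `saccmask_analysis` with elements `conditions`
#'   (named list of per-condition results), `summaries`
#'   (observer x condition table) and `anova` (accuracy, median SRT,
#'   minimum SRT).
#' @export
analyze_experiment <- function(trials, source_condition = "common_offset",
                               n_draws = 500, width_ms = 10, k = 5,
                               alpha = 0.05, timecourse = FALSE,
                               display_min_ms = 110) {
  check_condition(source_condition)
  if ("analyzable" %in% names(trials)) trials <- analyzable_trials(trials)
  present <- intersect(saccmask_conditions(), unique(trials$condition))
  if (!source_condition %in% present) {
    stop("source condition '", source_condition, "' absent from the data")
  }
  src <- trials[trials$condition == source_condition, , drop = FALSE]
  conditions <- list()
  for (cond in present) {
    d <- trials[trials$condition == cond, , drop = FALSE]
    res <- list(n_trials = nrow(d), accuracy = mean(d$correct),
                median_srt_ms = median_srt(d$srt_ms),
                min_srt = min_srt_by_observer(d, width_ms, k, alpha))
    if (cond != source_condition) {
      grid <- if (timecourse) {
        sort(d$srt_ms[d$srt_ms >= display_min_ms])
      }
      ens <- surrogate_ensemble(src, d, n_draws = n_draws,
                                width_ms = width_ms, k = k, alpha = alpha,
                                timecourse_grid = grid)
      res$surrogate <- surrogate_min_srt_ci(ens, res$min_srt$pooled)
      if (timecourse) {
        tc <- accuracy_timecourse(d, display_min_ms = display_min_ms)
        res$timecourse <- timecourse_comparison(tc, ens, alpha = alpha)
      }
    }
    conditions[[cond]] <- res
  }
  summaries <- observer_condition_summary(trials, width_ms, k, alpha)
  anova <- list()
  if (length(present) >= 2L && length(unique(trials$observer)) >= 2L) {
    # an ANOVA can be unavailable (e.g. minimum SRT undefined in most
    # cells); report NULL for that response rather than failing the run
    safe <- function(resp) tryCatch(one_way_anova(summaries, resp),
                                    error = function(e) NULL)
    anova <- list(accuracy = safe("accuracy"),
                  median_srt = safe("median_srt_ms"),
                  min_srt = safe("min_srt_ms"))
  }
  structure(list(conditions = conditions, summaries = summaries,
                 anova = anova, source_condition = source_condition),
            class = "saccmask_analysis")
}

#' @export
print.saccmask_analysis <- function(x, ...) {
  cat("Saccadic choice masking analysis\n")
  for (cond in names(x$conditions)) {
    r <- x$conditions[[cond]]
    cat(sprintf(
      "  %-13s n=%5d  accuracy=%.3f  median SRT=%.0f ms  min SRT=%s",
      cond, r$n_trials, r$accuracy, r$median_srt_ms,
      if (is.na(r$min_srt$pooled)) "undef" else
        paste0(r$min_srt$pooled, " ms")))
    if (!is.null(r$surrogate)) {
      cat(sprintf("  [surrogate CI %.0f-%.0f ms: %s]",
                  r$surrogate$lower, r$surrogate$upper, r$surrogate$flag))
    }
    cat("\n")
  }
  if (length(x$anova)) {
    parts <- vapply(names(x$anova), function(nm) {
      a <- x$anova[[nm]]
      if (is.null(a)) sprintf("%s: n/a", nm) else
        sprintf("%s F(%d,%d)=%.2f p=%.3g", nm, a$df_between, a$df_within,
                a$F, a$p)
    }, character(1))
    cat("  ANOVA  ", paste(parts, collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

#' Run the end-to-end pipeline
#'
#' Single seeded command tying simulate -> preprocess -> analyze ->
#' surrogate -> report together. Intermediate artifacts (trial table
#' CSV, analysis JSON) are always written so downstream checks can
#' assert on any stage; outputs are byte-stable for a fixed seed.
#'
#' @param mode `"simulate"` runs a fully synthetic experiment;
#'   `"reproduce_dataset"` analyses an existing preprocessed trial CSV
#'   (`input` path required); `"recover_parameters"` runs a synthetic
#'   experiment with a latency-dependent masking impairment and reports
#'   whether the surrogate test recovers it (escaping flags for the
#'   masked conditions, consistent for the time-uniform one).
#' @param out_dir Directory for artifacts (created if needed).
#' @param seed Root seed.
#' @param config An [experiment_config()]; its seed is overridden by
#'   `seed`.
#' @param observers Passed to [simulate_experiment()].
#' @param input CSV path for `"reproduce_dataset"`.
#' @param column_map Passed to [read_trials()].
#' @param n_draws Surrogate draws.
#' @param verbose Log per-stage counts to stderr.
#' @return The `saccmask_analysis`, invisibly; artifacts under
#'   `out_dir`: `trials.csv`, `analysis.json`.
#' @export
run_pipeline <- function(mode = c("simulate", "reproduce_dataset",
                                  "recover_parameters"),
                         out_dir = tempfile("saccmask_run_"),
                         seed = 1, config = NULL, observers = NULL,
                         input = NULL, column_map = NULL, n_draws = 500,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (verbose) message(sprintf(...))
  if (mode == "reproduce_dataset") {
    if (is.null(input)) stop("mode 'reproduce_dataset' requires an input CSV")
    trials <- read_trials(input, column_map = column_map)
    log("read %d trials from %s", nrow(trials), input)
    trials <- preprocess_trials(trials)
    staircases <- NULL
  } else {
    if (is.null(config)) config <- experiment_config()
    config$seed <- as.integer(seed)
    ex <- simulate_experiment(config, observers = observers)
    trials <- ex$trials
    log("simulated %d trials", nrow(trials))
    trials <- preprocess_trials(trials, staircases = ex$staircases)
  }
  log("analyzable: %d / %d trials (%.1f%%)", sum(trials$analyzable),
      nrow(trials), 100 * mean(trials$analyzable))
  write_trials(trials, file.path(out_dir, "trials.csv"))
  set.seed(seed + 500009L)  # surrogate stream, distinct from simulation
  analysis <- analyze_experiment(trials, n_draws = n_draws)
  report <- list(
    mode = mode, seed = seed,
    config = if (mode != "reproduce_dataset") unclass(config),
    n_draws = n_draws,
    software = paste0("saccmask ",
                      as.character(utils::packageVersion("saccmask"))),
    n_trials = nrow(trials), n_analyzable = sum(trials$analyzable),
    conditions = lapply(analysis$conditions, function(r) {
      out <- list(n_trials = r$n_trials, accuracy = r$accuracy,
                  median_srt_ms = r$median_srt_ms,
                  min_srt_pooled_ms = r$min_srt$pooled,
                  min_srt_mean_ms = r$min_srt$mean_across_observers)
      if (!is.null(r$surrogate)) {
        out$surrogate <- list(lower = r$surrogate$lower,
                              upper = r$surrogate$upper,
                              flag = r$surrogate$flag)
      }
      out
    }),
    anova = analysis$anova)
  jsonlite::write_json(report, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  log("wrote %s", file.path(out_dir, "analysis.json"))
  invisible(analysis)
}
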