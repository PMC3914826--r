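#' Observer-by-condition summary table
#'
#' One row per observer x condition: overall accuracy, median SRT and
#' minimum SRT, computed on analyzable trials. These summaries are the
#' observations entering the condition-level ANOVAs (with 4 observers
#' and 4 conditions the tests have df = 3, 12).
#'
#' @param trials Analyzable trial data frame (`observer`, `condition`,
#'   `srt_ms`, `correct`).
#' @param width_ms,k,alpha Minimum-SRT settings.
#' @return Data frame with columns `observer`, `condition`, `accuracy`,
#'   `median_srt_ms`, `min_srt_ms`.
#' @export
observer_condition_summary <- function(trials, width_ms = 10, k = 5,
                                       alpha = 0.05) {
  stopifnot(all(c("observer", "condition", "srt_ms", "correct") %in%
                  names(trials)))
  cells <- split(trials, list(trials$observer, trials$condition),
                 drop = TRUE)
  out <- lapply(cells, function(d) {
    data.frame(observer = d$observer[1L], condition = d$condition[1L],
               accuracy = mean(d$correct),
               median_srt_ms = median_srt(d$srt_ms),
               min_srt_ms = minimum_srt(
                 bin_srt(d$srt_ms, d$correct, width_ms),
                 k = k, alpha = alpha)$min_srt_ms)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$observer), , drop = FALSE]
}

#' One-way ANOVA across conditions
#'
#' Classical single-factor between/within decomposition of an
#' observer x condition summary variable, treating the summaries as
#' independent observations.
#'
#' @param summaries Output of [observer_condition_summary()] (or any
#'   data frame with a `condition` column).
#' @param response Name of the response column (e.g. `"accuracy"`,
#'   `"median_srt_ms"`, `"min_srt_ms"`).
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
#' @examples
#' s <- data.frame(condition = rep(c("a", "b"), each = 2),
#'                 accuracy = c(1, 2, 3, 4))
#' one_way_anova(s, "accuracy")$F  # 8
one_way_anova <- function(summaries, response) {
  stopifnot(response %in% names(summaries),
            "condition" %in% names(summaries))
  d <- summaries[stats::complete.cases(summaries[c(response, "condition")]), ]
  counts <- table(d$condition)
  if (length(counts) < 2L) stop("ANOVA requires at least 2 groups")
  if (any(counts == 0L)) stop("a group has zero observations")
  if (nrow(d) <= length(counts)) stop("no within-group degrees of freedom")
  fit <- stats::aov(stats::reformulate("condition", response), data = d)
  tab <- summary(fit)[[1L]]
  list(F = tab[["F value"]][1L], df_between = tab[["Df"]][1L],
       df_within = tab[["Df"]][2L], p = tab[["Pr(>F)"]][1L])
}

#' Tukey HSD pairwise comparisons across conditions
#'
#' Studentized-range-corrected pairwise mean comparisons following the
#' one-way ANOVA.
#'
#' @inheritParams one_way_anova
#' @param alpha Family significance level (default 0.05).
#' @return Data frame with columns `pair`, `diff`, `lwr`, `upr`,
#'   `p_adj`, `significant`.
#' @export
tukey_hsd <- function(summaries, response, alpha = 0.05) {
  stopifnot(response %in% names(summaries))
  d <- summaries[stats::complete.cases(summaries[c(response, "condition")]), ]
  d$condition <- factor(d$condition)
  fit <- stats::aov(stats::reformulate("condition", response), data = d)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$condition
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL)
}

#' Gamma GLM of SRT on contrast with reciprocal link
#'
#' Fits `1/E[SRT] = b0 + b1 * contrast` by iteratively reweighted least
#' squares (gamma family, inverse link) to quantify, on a single-trial
#' basis, whether staircase-driven contrast variations predict SRT. The
#' slope is reported with its Wald test (dispersion estimated by the
#' Pearson statistic, the [stats::summary.glm()] default for the gamma
#' family). A slope indistinguishable from 0 indicates that trial-to-
#' trial contrast variation does not account for SRT variability.
#'
#' @param contrast Per-trial contrast values.
#' @param srt_ms Per-trial SRTs (all > 0).
#' @return List with `beta0`, `beta1`, `se`, `t`, `p` (Wald test of
#'   `beta1 = 0`) and the fitted `model`.
#' @export
gamma_glm_reciprocal <- function(contrast, srt_ms) {
  stopifnot(length(contrast) == length(srt_ms))
  if (length(srt_ms) < 10L) stop("at least 10 trials are required")
  if (any(srt_ms <= 0)) stop("all SRTs must be positive")
  fit <- stats::glm(srt_ms ~ contrast,
                    family = stats::Gamma(link = "inverse"))
  if (!fit$converged) stop("gamma GLM did not converge after ",
                           fit$iter, " iterations")
  co <- summary(fit)$coefficients
  slope <- if ("contrast" %in% rownames(co)) co["contrast", ] else
    c(0, NA, NA, NA)
  list(beta0 = co["(Intercept)", 1L], beta1 = slope[[1L]],
       se = slope[[2L]], t = slope[[3L]], p = slope[[4L]], model = fit)
}
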