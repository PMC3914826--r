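#' Initialise a QUEST adaptive staircase
#'
#' Creates a Bayesian staircase state holding a discretised posterior over
#' the log10 threshold contrast of a Weibull psychometric function. Each
#' trial's contrast is placed so that the staircase expects performance at
#' `target_p` (see `recommend_rule`); after the outcome is observed the
#' posterior is updated by pointwise multiplication with the outcome
#' likelihood. All posterior arithmetic is carried out in the log domain
#' to avoid underflow.
#'
#' @param prior_mean Prior mean of the log10 threshold contrast.
#' @param prior_sd Prior standard deviation (log10 units); the grid spans
#'   `prior_mean +/- grid_span * prior_sd`.
#' @param target_p Proportion correct the staircase should hold the
#'   observer at; must lie strictly between `guess` and `1 - lapse`.
#' @param slope,guess,lapse Assumed Weibull family parameters
#'   (see [psychometric_p_correct()]).
#' @param grid_n Number of grid points for the posterior.
#' @param grid_span Half-width of the grid in prior standard deviations.
#' @param min_contrast Smallest contrast the display can produce;
#'   recommendations are clamped to `[min_contrast, 1]`.
#' @param recommend_rule How the next trial's contrast is placed:
#'   `"predictive"` (default) solves for the contrast at which the
#'   *posterior-predictive* psychometric function — the psychometric
#'   family averaged over the threshold posterior — attains `target_p`;
#'   because the posterior predictive is a calibrated forecast of the
#'   observed outcome frequencies, the realized accuracy tracks the
#'   target even when the assumed family is misspecified. `"mean"` and
#'   `"mode"` are classical plug-in rules using the function centred on
#'   the posterior-mean (or modal) threshold.
#' @return An object of class `quest_state`.
#' @seealso [quest_update()], [quest_recommend()], [quest_stable()]
#' @export
#' @examples
#' q <- quest_init(prior_mean = log10(0.2), prior_sd = 0.5, target_p = 0.82)
#' quest_recommend(q)
quest_init <- function(prior_mean = log10(0.2), prior_sd = 0.5,
                       target_p = 0.82, slope = 3.5, guess = 0.5,
                       lapse = 0.01, grid_n = 200, grid_span = 4,
                       min_contrast = 1e-4,
                       recommend_rule = c("predictive", "mean", "mode")) {
  stopifnot(prior_sd > 0, grid_n >= 10, grid_span > 0,
            min_contrast > 0, min_contrast < 1)
  recommend_rule <- match.arg(recommend_rule)
  if (target_p <= guess) {
    stop("target_p at or below the guess rate is unattainable for a ",
         "forced-choice task")
  }
  if (target_p >= 1 - lapse) {
    stop("target_p must be below 1 - lapse")
  }
  grid <- seq(prior_mean - grid_span * prior_sd,
              prior_mean + grid_span * prior_sd, length.out = grid_n)
  log_post <- stats::dnorm(grid, prior_mean, prior_sd, log = TRUE)
  log_post <- log_post - logsumexp(log_post)
  cap <- 256L
  structure(list(
    grid = grid,
    log_post = log_post,
    prior_mean = prior_mean,
    prior_sd = prior_sd,
    target_p = target_p,
    slope = slope,
    guess = guess,
    lapse = lapse,
    min_contrast = min_contrast,
    recommend_rule = recommend_rule,
    u_grid = 10^(-slope * grid),  # (threshold)^(-slope), precomputed
    n_trials = 0L,
    # preallocated history, grown geometrically
    h_contrast = numeric(cap),
    h_correct = logical(cap),
    h_post_mean = numeric(cap)
  ), class = "quest_state")
}

#' @export
print.quest_state <- function(x, ...) {
  cat(sprintf(
    "QUEST staircase: target p = %.2f, %d trials, posterior-mean log10 threshold = %.3f\n",
    x$target_p, x$n_trials, quest_posterior_mean(x)))
  invisible(x)
}

#' Posterior-mean log10 threshold of a QUEST state
#'
#' @param state A `quest_state` object.
#' @return Posterior mean of the log10 threshold contrast.
#' @export
quest_posterior_mean <- function(state) {
  sum(state$grid * exp(state$log_post))
}

#' Update a QUEST staircase with one trial outcome
#'
#' Multiplies the posterior pointwise by the likelihood of the observed
#' outcome under the Weibull psychometric family centred at each candidate
#' threshold, then renormalises. Because pointwise products commute, the
#' final posterior is invariant to the order in which a fixed set of
#' trials is applied.
#'
#' @param state A `quest_state` object.
#' @param contrast Contrast tested on this trial (> 0).
#' @param correct Logical; was the response correct?
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, contrast, correct) {
  stopifnot(inherits(state, "quest_state"), length(contrast) == 1L,
            is.finite(contrast), contrast > 0, length(correct) == 1L)
  correct <- as.logical(correct)
  p <- state$guess + (1 - state$guess - state$lapse) *
    (1 - exp(-(contrast / 10^state$grid)^state$slope))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  lp <- state$log_post + if (correct) log(p) else log1p(-p)
  lp <- lp - logsumexp(lp)
  if (any(!is.finite(lp))) {
    stop("non-finite posterior after update; the threshold grid does not ",
         "cover the data (grid misconfiguration)")
  }
  state$log_post <- lp
  n <- state$n_trials + 1L
  if (n > length(state$h_contrast)) {
    grow <- function(v) {
      length(v) <- 2L * length(v)
      v
    }
    state$h_contrast <- grow(state$h_contrast)
    state$h_correct <- grow(state$h_correct)
    state$h_post_mean <- grow(state$h_post_mean)
  }
  state$n_trials <- n
  state$h_contrast[n] <- contrast
  state$h_correct[n] <- correct
  state$h_post_mean[n] <- sum(state$grid * exp(lp))
  state
}

#' Contrast recommendation from a QUEST staircase
#'
#' Returns the contrast at which the staircase expects the observer to
#' perform at its target proportion correct, clamped to the displayable
#' range `[min_contrast, 1]`. Under the default `"predictive"` rule this
#' is the contrast where the posterior-predictive psychometric function
#' (the Weibull family averaged over the threshold posterior) attains
#' `target_p`, found by bisection on log contrast; the plug-in `"mean"`
#' and `"mode"` rules invert the function centred on a point estimate of
#' the threshold instead.
#'
#' @param state A `quest_state` object.
#' @return A single contrast value in `[min_contrast, 1]`.
#' @export
quest_recommend <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  rule <- state$recommend_rule
  if (is.null(rule)) rule <- "predictive"
  if (rule != "predictive") {
    thr <- if (rule == "mode") {
      10^state$grid[which.max(state$log_post)]
    } else {
      10^quest_posterior_mean(state)
    }
    c_rec <- psychometric_inverse(state$target_p, threshold = thr,
                                  slope = state$slope, guess = state$guess,
                                  lapse = state$lapse)
    return(min(max(c_rec, state$min_contrast), 1))
  }
  # posterior-predictive: solve E_T[exp(-(c/T)^slope)] = f*
  post <- exp(state$log_post)
  u <- state$u_grid
  fstar <- 1 - (state$target_p - state$guess) /
    (1 - state$guess - state$lapse)
  f_at <- function(lc) sum(post * exp(-exp(state$slope * lc) * u))
  lo <- log(state$min_contrast)
  hi <- 0
  if (f_at(hi) > fstar) return(1)             # target unreachable below c = 1
  if (f_at(lo) <= fstar) return(state$min_contrast)
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    if (f_at(mid) > fstar) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' Trial history of a QUEST staircase
#'
#' @param state A `quest_state` object.
#' @param window,tolerance Stability rule parameters passed to the
#'   per-trial `stable` column (see [quest_stable()]).
#' @return A data frame with one row per trial: `trial`, `contrast`,
#'   `correct`, `posterior_mean`, `stable`.
#' @export
quest_history <- function(state, window = 40, tolerance = 0.12) {
  stopifnot(inherits(state, "quest_state"))
  n <- state$n_trials
  idx <- seq_len(n)
  pm <- state$h_post_mean[idx]
  stable <- rep(FALSE, n)
  fs <- quest_first_stable(state, window = window, tolerance = tolerance)
  if (!is.na(fs)) stable[fs:n] <- TRUE
  data.frame(trial = idx, contrast = state$h_contrast[idx],
             correct = state$h_correct[idx], posterior_mean = pm,
             stable = stable)
}

#' Has a QUEST staircase arrived at a stable estimate?
#'
#' The estimate is called stable when the posterior-mean threshold has
#' ranged over less than `tolerance` log10 units across the last `window`
#' trials.
#'
#' @param state A `quest_state` object with at least `window` trials.
#' @param window Number of most recent trials inspected (>= 2).
#' @param tolerance Maximum allowed range of the posterior-mean log10
#'   threshold over the window.
#' @return Logical.
#' @export
quest_stable <- function(state, window = 40, tolerance = 0.12) {
  stopifnot(inherits(state, "quest_state"))
  if (window < 2) stop("stability window must be at least 2 trials")
  n <- state$n_trials
  if (n < window) return(FALSE)
  pm <- state$h_post_mean[(n - window + 1L):n]
  diff(range(pm)) < tolerance
}

#' First trial at which a QUEST staircase was stable
#'
#' @inheritParams quest_stable
#' @return The smallest trial index `i >= window` such that the
#'   posterior-mean threshold ranged over less than `tolerance` log10
#'   units during trials `i - window + 1, ..., i`, or `NA` if stability
#'   was never reached.
#' @export
quest_first_stable <- function(state, window = 40, tolerance = 0.12) {
  stopifnot(inherits(state, "quest_state"))
  if (window < 2) stop("stability window must be at least 2 trials")
  n <- state$n_trials
  if (n < window) return(NA_integer_)
  pm <- state$h_post_mean[seq_len(n)]
  # rolling range over windows of length `window`
  emb <- stats::embed(pm, window)
  rng <- apply(emb, 1L, function(v) diff(range(v)))
  hit <- which(rng < tolerance)
  if (!length(hit)) return(NA_integer_)
  hit[1L] + window - 1L
}

#' Run a simulated observer through a QUEST staircase
#'
#' Convenience driver used for calibration checks: on each trial the
#' staircase recommends a contrast, the simulated Weibull observer
#' responds with probability [psychometric_p_correct()] evaluated at its
#' own (true) parameters, and the staircase is updated.
#'
#' @param state A freshly initialised `quest_state`.
#' @param n_trials Number of trials to run.
#' @param observer Named list with the simulated observer's true
#'   `threshold`, `slope`, `guess`, `lapse`.
#' @return The final `quest_state`; retrieve per-trial results with
#'   [quest_history()].
#' @export
#' @examples
#' set.seed(1)
#' q <- quest_init(target_p = 0.82)
#' q <- quest_run_simulated(q, 200, list(threshold = 0.2, slope = 3.5,
#'                                       guess = 0.5, lapse = 0.01))
#' mean(quest_history(q)$correct)
quest_run_simulated <- function(state, n_trials, observer) {
  stopifnot(inherits(state, "quest_state"), n_trials >= 1)
  for (i in seq_len(n_trials)) {
    contrast <- quest_recommend(state)
    p <- psychometric_p_correct(contrast, threshold = observer$threshold,
                                slope = observer$slope,
                                guess = observer$guess,
                                lapse = observer$lapse)
    state <- quest_update(state, contrast, stats::runif(1) < p)
  }
  state
}
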