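#' Weibull psychometric function for a 2AFC task
#'
#' Probability of a correct response as a function of stimulus contrast,
#' using the Weibull family conventional for QUEST-style adaptive
#' procedures:
#' \deqn{p(c) = \gamma + (1 - \gamma - \lambda)\,\left[1 - e^{-(c/\alpha)^\beta}\right]}
#' where \eqn{\gamma} is the guess rate (0.5 for 2AFC), \eqn{\lambda} the
#' lapse rate, \eqn{\alpha} the threshold contrast and \eqn{\beta} the slope.
#'
#' @param contrast Stimulus contrast in `[0, 1]` (Michelson-like scale).
#'   Vectorised.
#' @param threshold Threshold contrast \eqn{\alpha > 0}.
#' @param slope Weibull slope \eqn{\beta > 0} (dimensionless).
#' @param guess Guess rate \eqn{\gamma}; 0.5 for a 2AFC task.
#' @param lapse Lapse rate \eqn{\lambda} in `[0, 1 - guess)`.
#' @return Probability of a correct response, bounded in
#'   `[guess, 1 - lapse]`, monotonically non-decreasing in `contrast`.
#' @export
#' @examples
#' psychometric_p_correct(0.2, threshold = 0.2, slope = 3.5, lapse = 0.01)
#' psychometric_p_correct(0, threshold = 0.2)  # chance: 0.5
psychometric_p_correct <- function(contrast, threshold = 0.2, slope = 3.5,
                                   guess = 0.5, lapse = 0.01) {
  if (any(!is.finite(contrast)) || any(contrast < 0) || any(contrast > 1)) {
    stop("contrast must lie in [0, 1]")
  }
  stopifnot(threshold > 0, slope > 0, guess >= 0, guess < 1,
            lapse >= 0, lapse < 1 - guess)
  guess + (1 - guess - lapse) * (1 - exp(-(contrast / threshold)^slope))
}

#' Contrast at which the Weibull psychometric function attains a target
#'
#' Inverse of [psychometric_p_correct()] in its contrast argument.
#'
#' @inheritParams psychometric_p_correct
#' @param p Target probability of a correct response, strictly between
#'   `guess` and `1 - lapse`.
#' @return The contrast yielding `p` (may exceed 1; callers clamp to the
#'   displayable range).
#' @export
psychometric_inverse <- function(p, threshold = 0.2, slope = 3.5,
                                 guess = 0.5, lapse = 0.01) {
  stopifnot(threshold > 0, slope > 0)
  if (any(p <= guess) || any(p >= 1 - lapse)) {
    stop("target p must lie strictly between guess and 1 - lapse")
  }
  frac <- (p - guess) / (1 - guess - lapse)
  threshold * (-log1p(-frac))^(1 / slope)
}
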