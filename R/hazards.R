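#' Convert a probability over a period to a constant annual rate
#'
#' Standard constant-hazard transform used throughout the model:
#' \code{r = -log(1 - p) / t}.  Inverse of [rate_to_prob()].
#'
#' @param p Probability of the event over the period, in `[0, 1)`.
#' @param t Period length in years (> 0).
#' @return Annual event rate (per person-year).
#' @seealso [rate_to_prob()], [rescale_prob()]
#' @export
#' @examples
#' prob_to_rate(0.0171, 0.25)
prob_to_rate <- function(p, t = 1) {
  stopifnot(t > 0)
  if (any(p < 0 | p >= 1)) {
    stop("prob_to_rate: probabilities must lie in [0, 1)")
  }
  -log1p(-p) / t
}

#' Convert a constant annual rate to a probability over a period
#'
#' @param r Annual event rate (>= 0).
#' @param t Period length in years (> 0).
#' @return Probability `1 - exp(-r * t)`.
#' @export
#' @examples
#' rate_to_prob(prob_to_rate(0.03), 0.25)  # annual 3% as one 3-month cycle
rate_to_prob <- function(r, t = 1) {
  stopifnot(t > 0)
  if (any(r < 0)) stop("rate_to_prob: rates must be non-negative")
  -expm1(-r * t)
}

#' Rescale a probability from one period to another under a constant hazard
#'
#' @param p Probability over `from` years.
#' @param from,to Period lengths in years.
#' @return Probability over `to` years: `1 - (1 - p)^(to/from)`.
#' @export
rescale_prob <- function(p, from = 1, to = 0.25) {
  rate_to_prob(prob_to_rate(p, from), to)
}

#' Apply a relative risk to a per-cycle probability
#'
#' The relative effect is applied on the hazard scale, so the result stays a
#' probability for any positive relative risk: the per-cycle probability is
#' converted to a rate, multiplied by `rr`, and converted back, which reduces
#' to \code{1 - (1 - p)^rr}.
#'
#' @param p_cycle Per-cycle probability in `[0, 1)`.
#' @param rr Relative risk (> 0, or 0 to switch the event off).
#' @return Adjusted per-cycle probability.
#' @export
#' @examples
#' apply_relative_risk(0.0171, 1.18)
apply_relative_risk <- function(p_cycle, rr) {
  if (any(rr < 0)) stop("apply_relative_risk: relative risks must be >= 0")
  if (any(p_cycle < 0 | p_cycle >= 1)) {
    stop("apply_relative_risk: probabilities must lie in [0, 1)")
  }
  -expm1(rr * log1p(-p_cycle))
}

#' Ageing multiplier on bleeding hazards
#'
#' Major and clinically relevant non-major bleeding hazards rise by a factor
#' of 1.97 per decade of life; the multiplier is anchored at the cohort age
#' when the adjustment switches on (after the first 18 model months, the
#' period covered directly by trial data).
#'
#' @param current_age Current cohort age in years.
#' @param reference_age Age at which the multiplier equals 1.
#' @param per_decade Multiplier per 10 years of age (default 1.97).
#' @return `per_decade ^ ((current_age - reference_age) / 10)`.
#' @export
age_bleed_multiplier <- function(current_age, reference_age, per_decade = 1.97) {
  stopifnot(per_decade > 0)
  per_decade^((current_age - reference_age) / 10)
}

#' Combine competing per-cycle risks into effective transition probabilities
#'
#' Marginal per-cycle probabilities are combined under an exponential-race
#' model: each marginal is converted to a constant hazard
#' \eqn{r_j = -\log(1 - p_j)}, the total event probability is
#' \eqn{P = 1 - \exp(-\sum r_j)}, and event \eqn{j} receives the share
#' \eqn{P r_j / \sum r_j}.  This guarantees at most one structural transition
#' per cycle and that the effective probabilities plus the stay probability
#' sum to exactly 1.
#'
#' @param p Numeric vector (possibly named) of marginal per-cycle
#'   probabilities, each in `[0, 1)`.
#' @return A list with `events` (effective per-event probabilities, same
#'   names/order as `p`) and `stay` (probability of no event).
#' @export
#' @examples
#' combine_competing(c(vte = 0.1, bleed = 0.2))
combine_competing <- function(p) {
  if (any(p < 0 | p >= 1)) {
    stop("combine_competing: marginal probabilities must lie in [0, 1)")
  }
  r <- -log1p(-p)
  rtot <- sum(r)
  if (rtot == 0) {
    return(list(events = p * 0, stay = 1))
  }
  total <- -expm1(-rtot)
  events <- total * r / rtot
  list(events = events, stay = 1 - sum(events))
}
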