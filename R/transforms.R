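#' Convert a probability to a constant hazard rate
#'
#' Converts the probability of an event occurring within `t` years into the
#' constant annual rate that would produce that probability under an
#' exponential waiting-time model: \eqn{r = -\ln(1 - p)/t}. Exact inverse of
#' [rate_to_prob()].
#'
#' @param p event probability, in `[0, 1)`. Vectorised.
#' @param t duration in years over which `p` applies (default 1).
#' @return rate per year (same length as `p`).
#' @export
#' @examples
#' prob_to_rate(0.5)        # log(2)
#' rate_to_prob(prob_to_rate(0.37))
prob_to_rate <- function(p, t = 1) {
  if (length(t) != 1L || !is.finite(t) || t <= 0) stop("'t' must be a single positive duration")
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("'p' must lie in [0, 1): a probability of 1 has no finite rate")
  }
  -log(1 - p) / t
}

#' Convert a constant hazard rate to a probability
#'
#' \eqn{p = 1 - e^{-rt}}: the probability of at least one event within `t`
#' years at constant annual rate `r`. Exact inverse of [prob_to_rate()].
#'
#' @param r rate per year, non-negative. Vectorised.
#' @param t duration in years (default 1).
#' @return probability in `[0, 1)`.
#' @export
rate_to_prob <- function(r, t = 1) {
  if (length(t) != 1L || !is.finite(t) || t <= 0) stop("'t' must be a single positive duration")
  if (any(!is.finite(r)) || any(r < 0)) stop("'r' must be a non-negative rate")
  1 - exp(-r * t)
}

#' Apply a hazard ratio to a transition probability
#'
#' Rescales a per-cycle transition probability on the complementary-log
#' scale, \eqn{p' = 1 - (1-p)^{\mathrm{hr}}}, which is equivalent to
#' multiplying the underlying constant hazard by `hr`. This is the standard
#' health-economics convention for carrying a trial hazard ratio (here, on
#' 6-month confirmed disability progression) onto model transition
#' probabilities. `hr = 1` leaves `p` unchanged; `p = 0` maps to 0 for any
#' `hr`.
#'
#' @param p transition probability in `[0, 1)`. Vectorised.
#' @param hr positive hazard ratio.
#' @return adjusted probability in `[0, 1)`.
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (length(hr) != 1L || !is.finite(hr) || hr <= 0) stop("'hr' must be a single positive hazard ratio")
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("'p' must lie in [0, 1): a certain transition cannot be hazard-adjusted")
  }
  if (hr == 1) return(p)  # exact identity, no floating-point round trip
  1 - (1 - p)^hr
}

#' Present-value discount factor
#'
#' \eqn{(1 + \mathrm{rate})^{-\mathrm{year}}}, with year 0 the present
#' (factor 1).
#'
#' @param year integer year index, `>= 0`. Vectorised.
#' @param rate annual discount rate as a fraction (e.g. 0.03), `>= 0`.
#' @return dimensionless discount factor in `(0, 1]`.
#' @export
discount_factor <- function(year, rate) {
  if (length(rate) != 1L || !is.finite(rate) || rate < 0) stop("'rate' must be a single non-negative fraction")
  if (any(!is.finite(year)) || any(year < 0)) stop("'year' must be non-negative")
  (1 + rate)^(-year)
}
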