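# Clinical, DALY, informal-care and productivity outcomes from a trace.
#
# Conventions (fixed, documented in the methods vignette):
#  - end-of-horizon shares are read at the final cycle among survivors;
#  - natural-unit time aggregates (years in band, informal-care days,
#    relapse counts) run over cycles 1..horizon, undiscounted;
#  - DALY components are discounted at the effects rate, with state-years
#    (YLD) valued at start-of-cycle membership (years 0..horizon-1) and
#    deaths in the cycle ending at year t discounted to year t-1.

EDSS_BANDS <- list(
  mild = 0:3,        # no or mild disability
  walking_aid = 4:6, # walking aid needed (half-point 6.5 rounds down to 6)
  wheelchair = 7L,
  bedridden = 8:9
)

band_mass <- function(state, band) {
  sum(living_by_edss(state)[band + 1L])
}

#' Shares of survivors by EDSS band
#'
#' Living occupancy at the given year aggregated into the disability bands
#' mild (EDSS 0-3), walking aid (4-6), wheelchair (7) and bedridden (8-9),
#' normalised by living mass so the four bands sum to 1. The derived
#' `immobile` entry (EDSS 7-9) is the wheelchair + bedridden sum.
#'
#' @param trace a `cohort_trace`.
#' @param year cycle index, `0 <= year <= horizon` (default: horizon).
#' @return named numeric: `mild`, `walking_aid`, `wheelchair`, `bedridden`,
#'   `immobile`.
#' @export
edss_band_shares <- function(trace, year = trace$horizon) {
  stopifnot(inherits(trace, "cohort_trace"), year >= 0, year <= trace$horizon)
  st <- trace$states[[year + 1L]]
  alive <- living_mass(st)
  if (alive <= 0) stop(sprintf("no survivors at year %d: band shares are undefined", year))
  shares <- vapply(EDSS_BANDS, function(b) band_mass(st, b), 0) / alive
  c(shares, immobile = unname(shares["wheelchair"] + shares["bedridden"]))
}

#' Mean EDSS among survivors
#'
#' @param trace a `cohort_trace`.
#' @param year cycle index (default: horizon).
#' @return occupancy-weighted mean of the integer EDSS scores.
#' @export
mean_edss <- function(trace, year = trace$horizon) {
  stopifnot(inherits(trace, "cohort_trace"), year >= 0, year <= trace$horizon)
  st <- trace$states[[year + 1L]]
  alive <- living_mass(st)
  if (alive <= 0) stop(sprintf("no survivors at year %d: mean EDSS is undefined", year))
  sum(EDSS_STATES * living_by_edss(st)) / alive
}

#' Undiscounted patient-years spent in an EDSS band
#'
#' Sums living band occupancy over cycles 1..horizon (the baseline snapshot
#' is excluded so that a cohort alive in the band for the whole run scores
#' exactly `horizon` years).
#'
#' @param trace a `cohort_trace`.
#' @param band integer vector of EDSS states, e.g. `0:3`.
#' @return years per patient.
#' @export
years_in_band <- function(trace, band) {
  stopifnot(inherits(trace, "cohort_trace"), all(band %in% EDSS_STATES))
  sum(vapply(seq_len(trace$horizon), function(t) {
    band_mass(trace$states[[t + 1L]], band)
  }, 0))
}

#' Years of life lost (YLL)
#'
#' Deaths in each cycle weighted by the remaining age- and sex-specific
#' general-population life expectancy at the time of death, discounted to
#' present at the effects rate. The life-expectancy lookup uses the same
#' floored integer age as the cycle's mortality lookup.
#'
#' @param trace a `cohort_trace`.
#' @param mortality the [mortality_model()] the trace was run with.
#' @param discount_rate annual effects discount rate (fraction).
#' @return discounted years per patient.
#' @export
compute_yll <- function(trace, mortality, discount_rate = 0) {
  stopifnot(inherits(trace, "cohort_trace"))
  base_age <- floor(trace$start_age)
  total <- 0
  for (t in seq_len(trace$horizon)) {
    age_at_death <- as.integer(base_age + t - 1L)
    for (sex in SEXES) {
      d <- unname(trace$new_deaths[t, sex])
      if (d > 0) {
        total <- total + d * mort_ex(mortality, age_at_death, sex) *
          discount_factor(t - 1L, discount_rate)
      }
    }
  }
  total
}

#' Years lived with disability (YLD)
#'
#' Living state-years weighted by the per-EDSS disability weights,
#' discounted at the effects rate; membership is valued at the start of
#' each cycle (years 0..horizon-1, no half-cycle correction).
#'
#' @param trace a `cohort_trace`.
#' @param weights numeric length-10 disability weights per EDSS 0-9, or a
#'   [state_valuation()] from which they are taken.
#' @param discount_rate annual effects discount rate (fraction).
#' @return discounted years per patient.
#' @export
compute_yld <- function(trace, weights, discount_rate = 0) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (inherits(weights, "state_valuation")) weights <- weights$table$disability_weight
  stopifnot(length(weights) == N_EDSS)
  total <- 0
  for (t in seq_len(trace$horizon)) {
    occ <- living_by_edss(trace$states[[t]])  # start-of-cycle state, year t-1
    total <- total + sum(occ * weights) * discount_factor(t - 1L, discount_rate)
  }
  total
}

#' Total expected relapses over the horizon
#'
#' @param trace a `cohort_trace`.
#' @return undiscounted expected relapse count per patient.
#' @export
total_relapses <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  sum(trace$expected_relapses)
}

#' Productivity shares and informal-care utilisation
#'
#' End-of-horizon employment, full-time and invalidity-pension shares are
#' occupancy-weighted per-EDSS proportions among survivors, defined only
#' while the cohort is below retirement age (otherwise reported as 0 with
#' `working_age = FALSE`). Informal-care days accumulate undiscounted over
#' cycles 1..horizon.
#'
#' @param trace a `cohort_trace`.
#' @param valuation a [state_valuation()].
#' @param retirement_age retirement age in years.
#' @return list with `employed`, `fulltime`, `invalidity` (proportions),
#'   `informal_care_days` (days per patient), `working_age` (logical flag).
#' @export
productivity_and_informal_care <- function(trace, valuation, retirement_age) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(valuation, "state_valuation"))
  tb <- valuation$table
  fin <- trace$states[[trace$horizon + 1L]]
  alive <- living_mass(fin)
  working_age <- fin$current_age < retirement_age
  if (working_age && alive > 0) {
    w <- living_by_edss(fin) / alive
    employed <- sum(w * tb$employed_fraction)
    fulltime <- sum(w * tb$fulltime_fraction)
    invalidity <- sum(w * tb$invalidity_fraction)
  } else {
    employed <- fulltime <- invalidity <- 0
  }
  days <- sum(vapply(seq_len(trace$horizon), function(t) {
    sum(living_by_edss(trace$states[[t + 1L]]) * tb$informal_care_days)
  }, 0))
  list(employed = employed, fulltime = fulltime, invalidity = invalidity,
       informal_care_days = days, working_age = working_age)
}

#' Full clinical/productivity outcome report for one trace
#'
#' Assembles the end-of-horizon EDSS band shares, the mean-EDSS-by-year
#' series, undiscounted years per band, total relapses, discounted DALY
#' components (DALY = YLD + YLL by construction), and productivity /
#' informal-care outputs.
#'
#' @param trace a `cohort_trace`.
#' @param params the [parameter_set()] the trace was run with.
#' @return an object of class `outcome_report`.
#' @export
outcome_report <- function(trace, params) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(params, "parameter_set"))
  eff_rate <- params$economics$discount_rate_effects
  yld <- compute_yld(trace, params$valuation, eff_rate)
  yll <- compute_yll(trace, params$mortality, eff_rate)
  prod <- productivity_and_informal_care(trace, params$valuation,
                                         params$economics$retirement_age)
  structure(
    list(
      scenario = trace$scenario$label,
      band_shares = edss_band_shares(trace),
      mean_edss_by_year = vapply(0:trace$horizon, function(t) mean_edss(trace, t), 0),
      years_in_band = vapply(EDSS_BANDS, function(b) years_in_band(trace, b), 0),
      total_relapses = total_relapses(trace),
      yld = yld, yll = yll, daly = yld + yll,
      informal_care_days = prod$informal_care_days,
      employed = prod$employed, fulltime = prod$fulltime,
      invalidity = prod$invalidity, working_age = prod$working_age
    ),
    class = "outcome_report"
  )
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("<outcome_report> %s\n", x$scenario))
  s <- x$band_shares
  cat(sprintf("  EDSS 0-3 %.1f%% | 4-6 %.1f%% | 7 %.1f%% | 8-9 %.1f%% (immobile %.1f%%)\n",
              100 * s["mild"], 100 * s["walking_aid"], 100 * s["wheelchair"],
              100 * s["bedridden"], 100 * s["immobile"]))
  cat(sprintf("  DALYs %.3f (YLD %.3f + YLL %.3f); relapses %.2f/patient\n",
              x$daly, x$yld, x$yll, x$total_relapses))
  cat(sprintf("  informal care %.1f days; employed %.1f%%, full-time %.1f%%, invalidity %.1f%%%s\n",
              x$informal_care_days, 100 * x$employed, 100 * x$fulltime,
              100 * x$invalidity,
              if (x$working_age) "" else " (cohort past retirement age)"))
  invisible(x)
}
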