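# Published reference values used for arithmetic-consistency checks.

#' Published reference results for the immediate-OMB scenario
#'
#' The printed per-patient results of a published 10-year German
#' societal-perspective cost-consequence analysis of immediate ofatumumab
#' treatment in relapsing MS: end-of-horizon EDSS band shares, DALY
#' components, relapse count, informal-care days and productivity shares;
#' the discounted cost breakdown by category (EUR); and the printed
#' percentage cost shares. These are *inputs* for consistency checks of the
#' report arithmetic (subtotals, totals, DALY decomposition, share
#' denominators) - the underlying supplementary input tables are not
#' public, so the package does not attempt to reproduce these values from
#' scratch.
#'
#' @return a list with elements `outcomes` (named numeric), `costs` (named
#'   numeric, EUR per patient, discounted) and `cost_shares_pct` (named
#'   numeric, percent, as printed at one decimal).
#' @export
reference_results <- function() {
  list(
    outcomes = c(
      mild_pct = 76.1, walking_aid_pct = 18.0, wheelchair_pct = 2.4,
      bedridden_pct = 3.5, immobile_pct = 5.9,
      dalys = 1.49, yld = 0.86, yll = 0.63,
      relapses = 2.15, informal_care_days = 168.38,
      employed_pct = 62.3, fulltime_pct = 36.7, invalidity_pct = 26.5
    ),
    costs = c(
      dmt = 145918, inpatient_care = 14963, day_care = 1281,
      consultations = 10125, tests_investigations = 2866, medications = 5270,
      community_social_services = 4815, investments_equipment_aids = 4463,
      informal_care = 15220,
      sum_direct = 204921,
      short_term_absence = 5617, long_term_absence = 83932,
      sum_indirect = 89549,
      sum_direct_indirect = 294470,
      relapse_costs = 5028,
      total = 299498
    ),
    cost_shares_pct = c(
      dmt = 71.2, inpatient_care = 7.3, day_care = 0.6, consultations = 4.9,
      tests_investigations = 1.4, medications = 2.6,
      community_social_services = 2.3, investments_equipment_aids = 2.2,
      informal_care = 7.4,
      sum_direct = 69.6,
      short_term_absence = 6.3, long_term_absence = 93.7,
      sum_indirect = 30.4,
      relapse_costs = 1.7
    )
  )
}
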