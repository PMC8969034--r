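# Discounted per-patient cost accumulation and Table-style cost reports.
#
# Costs attach to state membership at the start of each cycle (years
# 0..horizon-1, discount factor (1+r)^-t); per-cycle event quantities
# (relapses) for the cycle ending at year t are discounted at year t-1.

#' Discounted DMT acquisition costs over a scenario
#'
#' On-treatment living mass at the start of each cycle times the annual
#' price of the active treatment. The "year 1" price tier applies in the
#' first year of each contiguous run of a treatment within the scenario
#' (so after a mid-horizon switch the new drug's loading-year price is
#' charged once); the subsequent-year price applies after. Off-treatment
#' mass accrues nothing.
#'
#' @param trace a `cohort_trace`.
#' @param treatments named list of [treatment_effect()] objects.
#' @param spec the [scenario_spec()] the trace was run under.
#' @param rate annual cost discount rate (fraction).
#' @return discounted currency per patient.
#' @export
dmt_costs <- function(trace, treatments, spec = trace$scenario, rate = 0) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(spec, "scenario_spec"))
  runs <- treatment_run_starts(spec)
  total <- 0
  for (t in seq_len(trace$horizon)) {
    trt <- treatments[[runs$active[t]]]
    price <- if ((t - 1L) == runs$run_start[t]) trt$annual_drug_cost_year1
             else trt$annual_drug_cost_subsequent
    if (price == 0) next
    on_mass <- sum(trace$states[[t]]$occupancy[, "on", ])  # start-of-cycle
    total <- total + on_mass * price * discount_factor(t - 1L, rate)
  }
  total
}

#' Discounted per-EDSS state costs by category
#'
#' Accumulates the eight non-DMT direct categories and the two indirect
#' productivity-loss categories over start-of-cycle living occupancy,
#' discounted. Indirect costs accrue only while the cohort is below
#' retirement age.
#'
#' @param trace a `cohort_trace`.
#' @param valuation a [state_valuation()].
#' @param rate annual cost discount rate (fraction).
#' @param retirement_age retirement age in years (default 67).
#' @return list with named numeric vectors `direct` (8 categories) and
#'   `indirect` (2 categories), discounted currency per patient.
#' @export
state_cost_accumulation <- function(trace, valuation, rate = 0, retirement_age = 67) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(valuation, "state_valuation"))
  tb <- valuation$table
  direct <- stats::setNames(numeric(length(DIRECT_COST_CATEGORIES)), DIRECT_COST_CATEGORIES)
  indirect <- stats::setNames(numeric(2L), INDIRECT_COST_CATEGORIES)
  for (t in seq_len(trace$horizon)) {
    st <- trace$states[[t]]  # start-of-cycle state, year t-1
    occ <- living_by_edss(st)
    df <- discount_factor(t - 1L, rate)
    for (cat in DIRECT_COST_CATEGORIES) {
      direct[cat] <- direct[cat] + sum(occ * tb[[cat]]) * df
    }
    if (st$current_age < retirement_age) {
      indirect["short_term_absence"] <- indirect["short_term_absence"] +
        sum(occ * tb$short_term_absence_cost) * df
      indirect["long_term_absence"] <- indirect["long_term_absence"] +
        sum(occ * tb$long_term_absence_cost) * df
    }
  }
  list(direct = direct, indirect = indirect)
}

#' Discounted relapse costs
#'
#' Expected relapses per cycle times the societal unit cost per relapse
#' (base case 2662 EUR), discounted. Reported separately from (and in the
#' total added on top of) the state-membership costs, because the published
#' per-state cost inputs already contain an unknown share of relapse-related
#' spending.
#'
#' @param trace a `cohort_trace`.
#' @param annual_relapse_cost currency per relapse event.
#' @param rate annual cost discount rate (fraction).
#' @return discounted currency per patient.
#' @export
relapse_costs <- function(trace, annual_relapse_cost, rate = 0) {
  stopifnot(inherits(trace, "cohort_trace"))
  sum(trace$expected_relapses * annual_relapse_cost *
        discount_factor(seq_len(trace$horizon) - 1L, rate))
}

#' Assemble a cost report from its components
#'
#' Builds the full cost breakdown: direct categories (DMT plus the eight
#' state-cost categories) with subtotal, indirect categories with subtotal,
#' their combined sum, relapse costs, the grand total (combined + relapse;
#' an acknowledged overestimate since the state-cost inputs partially
#' include relapse spending), and percentage shares (each category over its
#' subtotal; each subtotal and the relapse cost over the combined
#' direct+indirect sum). Shares are held at full precision; rounding is a
#' printing concern.
#'
#' @param dmt discounted DMT cost (currency).
#' @param state_costs list as returned by [state_cost_accumulation()].
#' @param relapse discounted relapse cost (currency).
#' @param scenario optional scenario label carried into the report.
#' @return an object of class `cost_report`.
#' @export
build_cost_report <- function(dmt, state_costs, relapse, scenario = NA_character_) {
  stopifnot(is.numeric(dmt), length(dmt) == 1L, is.numeric(relapse), length(relapse) == 1L)
  if (!identical(names(state_costs$direct), DIRECT_COST_CATEGORIES) ||
      !identical(names(state_costs$indirect), INDIRECT_COST_CATEGORIES)) {
    stop("state_costs must carry exactly the expected direct and indirect categories")
  }
  direct <- c(dmt = unname(dmt), state_costs$direct)
  indirect <- state_costs$indirect
  direct_sub <- sum(direct)
  indirect_sub <- sum(indirect)
  combined <- direct_sub + indirect_sub
  total <- combined + relapse
  pct <- function(x, denom) if (denom > 0) 100 * x / denom else x * 0
  structure(
    list(
      scenario = scenario,
      direct = direct, direct_subtotal = direct_sub,
      indirect = indirect, indirect_subtotal = indirect_sub,
      direct_plus_indirect = combined,
      relapse_costs = relapse,
      total = total,
      shares = list(
        direct = pct(direct, direct_sub),
        indirect = pct(indirect, indirect_sub),
        direct_subtotal = pct(direct_sub, combined),
        indirect_subtotal = pct(indirect_sub, combined),
        relapse = pct(relapse, combined)
      )
    ),
    class = "cost_report"
  )
}

#' Full discounted cost report for one trace
#'
#' Convenience wrapper running [dmt_costs()], [state_cost_accumulation()]
#' and [relapse_costs()] at the parameter set's cost discount rate and
#' assembling them with [build_cost_report()].
#'
#' @param trace a `cohort_trace`.
#' @param params the [parameter_set()] the trace was run with.
#' @return an object of class `cost_report`.
#' @export
cost_report <- function(trace, params) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(params, "parameter_set"))
  rate <- params$economics$discount_rate_costs
  build_cost_report(
    dmt = dmt_costs(trace, params$treatments, trace$scenario, rate),
    state_costs = state_cost_accumulation(trace, params$valuation, rate,
                                          params$economics$retirement_age),
    relapse = relapse_costs(trace, params$economics$annual_relapse_cost, rate),
    scenario = trace$scenario$label
  )
}

COST_CATEGORY_LABELS <- c(
  dmt = "DMT costs",
  inpatient_care = "Inpatient care",
  day_care = "Day care admissions",
  consultations = "Consultations",
  tests_investigations = "Tests & investigations",
  medications = "Medications",
  community_social_services = "Community & social services",
  investments_equipment_aids = "Investments, equipment & aids",
  informal_care = "Informal care",
  short_term_absence = "Short-term absence",
  long_term_absence = "Long-term absence, invalidity & early retirement"
)

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> %s (discounted, per patient)\n",
              if (is.na(x$scenario)) "" else x$scenario))
  for (nm in names(x$direct)) {
    cat(sprintf("  %-48s %12.0f  (%5.1f%% of direct)\n",
                COST_CATEGORY_LABELS[nm], x$direct[nm], x$shares$direct[nm]))
  }
  cat(sprintf("  %-48s %12.0f  (%5.1f%% of direct+indirect)\n",
              "Sum direct costs", x$direct_subtotal, x$shares$direct_subtotal))
  for (nm in names(x$indirect)) {
    cat(sprintf("  %-48s %12.0f  (%5.1f%% of indirect)\n",
                COST_CATEGORY_LABELS[nm], x$indirect[nm], x$shares$indirect[nm]))
  }
  cat(sprintf("  %-48s %12.0f  (%5.1f%% of direct+indirect)\n",
              "Sum indirect costs", x$indirect_subtotal, x$shares$indirect_subtotal))
  cat(sprintf("  %-48s %12.0f\n", "Sum direct/indirect costs", x$direct_plus_indirect))
  cat(sprintf("  %-48s %12.0f  (%5.1f%% of direct+indirect)\n",
              "Relapse costs", x$relapse_costs, x$shares$relapse))
  cat(sprintf("  %-48s %12.0f\n", "Total costs", x$total))
  cat("  Note: state-cost inputs partly include relapse-related spending;\n")
  cat("  adding the separate relapse estimate makes the total an overestimate.\n")
  invisible(x)
}
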