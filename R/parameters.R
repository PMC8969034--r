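# Model-input domain types: constructors, validation, file I/O.
#
# All containers are plain lists with an S3 class. Public constructors
# validate immediately; load_parameter_set() builds everything unvalidated
# first and then reports *all* violations at once.

EDSS_STATES <- 0:9
N_EDSS <- 10L
SEXES <- c("male", "female")

# Direct (non-DMT) annual cost categories carried per EDSS state.
DIRECT_COST_CATEGORIES <- c(
  "inpatient_care", "day_care", "consultations", "tests_investigations",
  "medications", "community_social_services", "investments_equipment_aids",
  "informal_care"
)
INDIRECT_COST_CATEGORIES <- c("short_term_absence", "long_term_absence")

VALUATION_COLUMNS <- c(
  "edss", "disability_weight", DIRECT_COST_CATEGORIES, "informal_care_days",
  "employed_fraction", "fulltime_fraction", "invalidity_fraction",
  "short_term_absence_cost", "long_term_absence_cost"
)

ROW_SUM_TOL <- 1e-9

`%||%` <- function(a, b) if (is.null(a)) b else a

# Renormalise only rows that are measurably off 1 (beyond summation noise)
# but within the load tolerance; rows already at 1 to 1e-12 are left
# bit-untouched so that a load -> write -> load round trip is exact.
renormalize_rows <- function(m) {
  rs <- rowSums(m)
  fix <- abs(rs - 1) > 1e-12
  if (any(fix)) m[fix, ] <- m[fix, , drop = FALSE] / rs[fix]
  m
}

new_baseline_cohort <- function(edss_distribution, start_age, male_fraction,
                                cohort_size) {
  structure(
    list(
      edss_distribution = as.numeric(edss_distribution),
      start_age = as.numeric(start_age),
      male_fraction = as.numeric(male_fraction),
      cohort_size = as.numeric(cohort_size)
    ),
    class = "baseline_cohort"
  )
}

validate_baseline_cohort <- function(x) {
  bad <- character()
  d <- x$edss_distribution
  if (length(d) != 7L) {
    bad <- c(bad, sprintf("baseline$edss_distribution: must have 7 entries (EDSS 0-6), got %d", length(d)))
  } else {
    if (any(!is.finite(d)) || any(d < 0)) bad <- c(bad, "baseline$edss_distribution: entries must be non-negative")
    else if (abs(sum(d) - 1) > 1e-12) bad <- c(bad, sprintf("baseline$edss_distribution: must sum to 1 (got %.15g)", sum(d)))
  }
  if (!is.finite(x$start_age) || x$start_age <= 0) bad <- c(bad, "baseline$start_age: must be > 0")
  if (!is.finite(x$male_fraction) || x$male_fraction < 0 || x$male_fraction > 1) {
    bad <- c(bad, "baseline$male_fraction: must lie in [0, 1]")
  }
  if (!is.finite(x$cohort_size) || x$cohort_size <= 0) bad <- c(bad, "baseline$cohort_size: must be > 0")
  bad
}

#' Baseline cohort description
#'
#' The starting population of the simulation: a probability distribution over
#' integer EDSS 0-6 (the model admits baseline EDSS up to 6 only), a mean
#' starting age, the male fraction, and a nominal cohort size used solely to
#' scale population-level (as opposed to per-patient) outputs.
#'
#' @param edss_distribution numeric length-7 probability vector over EDSS
#'   0-6; must sum to 1.
#' @param start_age mean cohort age in years at model entry.
#' @param male_fraction proportion of males in `[0, 1]`.
#' @param cohort_size nominal number of patients (reporting scale only).
#' @return an object of class `baseline_cohort`.
#' @export
baseline_cohort <- function(edss_distribution, start_age, male_fraction,
                            cohort_size = 1000) {
  x <- new_baseline_cohort(edss_distribution, start_age, male_fraction, cohort_size)
  stop_on_violations(validate_baseline_cohort(x))
  x
}

new_natural_history <- function(transition_matrix, arr_by_edss) {
  m <- as.matrix(transition_matrix)
  dimnames(m) <- list(EDSS_STATES, EDSS_STATES)
  structure(
    list(transition_matrix = m, arr_by_edss = as.numeric(arr_by_edss)),
    class = "natural_history"
  )
}

validate_natural_history <- function(x) {
  bad <- character()
  m <- x$transition_matrix
  if (!is.matrix(m) || any(dim(m) != N_EDSS)) {
    bad <- c(bad, sprintf("natural_history$transition_matrix: must be 10x10 (EDSS 0-9), got %s",
                          paste(dim(m), collapse = "x")))
    return(bad)
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    bad <- c(bad, "natural_history$transition_matrix: entries must lie in [0, 1]")
  } else {
    rs <- rowSums(m)
    off <- which(abs(rs - 1) > ROW_SUM_TOL)
    for (i in off) {
      bad <- c(bad, sprintf("natural_history$transition_matrix: row for EDSS %d sums to %.12g, not 1", i - 1L, rs[i]))
    }
  }
  if (length(x$arr_by_edss) != N_EDSS) {
    bad <- c(bad, "natural_history$arr_by_edss: must have one rate per EDSS 0-9")
  } else if (any(!is.finite(x$arr_by_edss)) || any(x$arr_by_edss < 0)) {
    bad <- c(bad, "natural_history$arr_by_edss: rates must be non-negative")
  }
  bad
}

#' Natural-history disease model
#'
#' Annual EDSS transition probabilities for an untreated cohort plus the
#' untreated annualised relapse rate (ARR) in each state. Rows within the
#' row-sum tolerance (1e-9) are renormalised exactly on construction; rows
#' further off are rejected.
#'
#' @param transition_matrix 10x10 row-stochastic matrix over integer EDSS
#'   0-9; entry `[i, j]` is the annual probability of moving from EDSS `i-1`
#'   to EDSS `j-1` conditional on survival.
#' @param arr_by_edss numeric length-10: expected relapses per untreated
#'   patient-year in each EDSS state.
#' @return an object of class `natural_history`.
#' @export
natural_history <- function(transition_matrix, arr_by_edss) {
  x <- new_natural_history(transition_matrix, arr_by_edss)
  stop_on_violations(validate_natural_history(x))
  x$transition_matrix <- renormalize_rows(x$transition_matrix)
  x
}

new_treatment_effect <- function(name, hr_progression, rr_relapse,
                                 annual_drug_cost_year1, annual_drug_cost_subsequent) {
  structure(
    list(
      name = as.character(name),
      hr_progression = as.numeric(hr_progression),
      rr_relapse = as.numeric(rr_relapse),
      annual_drug_cost_year1 = as.numeric(annual_drug_cost_year1),
      annual_drug_cost_subsequent = as.numeric(annual_drug_cost_subsequent)
    ),
    class = "treatment_effect"
  )
}

validate_treatment_effect <- function(x) {
  bad <- character()
  pre <- sprintf("treatment '%s'", x$name)
  if (!nzchar(x$name)) bad <- c(bad, "treatment: name must be non-empty")
  if (!is.finite(x$hr_progression) || x$hr_progression <= 0) bad <- c(bad, paste0(pre, ": hr_progression must be > 0"))
  if (!is.finite(x$rr_relapse) || x$rr_relapse <= 0) bad <- c(bad, paste0(pre, ": rr_relapse must be > 0"))
  for (f in c("annual_drug_cost_year1", "annual_drug_cost_subsequent")) {
    if (!is.finite(x[[f]]) || x[[f]] < 0) bad <- c(bad, sprintf("%s: %s must be >= 0", pre, f))
  }
  if (identical(x$name, "none")) {
    if (x$hr_progression != 1 || x$rr_relapse != 1) bad <- c(bad, "treatment 'none': must have hr_progression = rr_relapse = 1")
    if (x$annual_drug_cost_year1 != 0 || x$annual_drug_cost_subsequent != 0) bad <- c(bad, "treatment 'none': must have zero drug cost")
  }
  bad
}

#' Treatment effect and price schedule
#'
#' A disease-modifying therapy (DMT) as the model sees it: a hazard ratio on
#' EDSS-worsening transitions (from 6-month confirmed disability
#' progression, 6-CDP), a rate ratio on the annualised relapse rate, and a
#' two-tier annual price (first year of use vs. subsequent years). The
#' reserved name `"none"` denotes untreated/off-treatment and forces
#' `hr = rr = 1` with zero cost.
#'
#' @param name treatment label, e.g. `"OMB"`, `"DMF"`, `"GA"`, `"none"`.
#' @param hr_progression positive hazard ratio applied to all
#'   EDSS-worsening transition probabilities (values < 1 slow progression).
#' @param rr_relapse positive rate ratio on the natural-history ARR.
#' @param annual_drug_cost_year1,annual_drug_cost_subsequent annual
#'   acquisition cost (EUR) in the first year on this drug and thereafter.
#' @return an object of class `treatment_effect`.
#' @export
treatment_effect <- function(name, hr_progression = 1, rr_relapse = 1,
                             annual_drug_cost_year1 = 0,
                             annual_drug_cost_subsequent = annual_drug_cost_year1) {
  x <- new_treatment_effect(name, hr_progression, rr_relapse,
                            annual_drug_cost_year1, annual_drug_cost_subsequent)
  stop_on_violations(validate_treatment_effect(x))
  x
}

new_mortality_model <- function(life_table, ms_hazard_ratio) {
  lt <- as.data.frame(life_table)
  if ("age" %in% names(lt)) lt$age <- as.integer(lt$age)
  for (col in setdiff(names(lt), "age")) lt[[col]] <- as.numeric(lt[[col]])
  structure(
    list(life_table = lt, ms_hazard_ratio = as.numeric(ms_hazard_ratio)),
    class = "mortality_model"
  )
}

validate_mortality_model <- function(x) {
  bad <- character()
  lt <- x$life_table
  need <- c("age", "q_male", "q_female", "ex_male", "ex_female")
  miss <- setdiff(need, names(lt))
  if (length(miss)) {
    bad <- c(bad, sprintf("mortality$life_table: missing column(s) %s", paste(miss, collapse = ", ")))
    return(bad)
  }
  if (nrow(lt) < 2L || any(diff(lt$age) != 1L)) {
    bad <- c(bad, "mortality$life_table: ages must be consecutive integers")
  }
  for (qc in c("q_male", "q_female")) {
    if (any(!is.finite(lt[[qc]])) || any(lt[[qc]] < 0) || any(lt[[qc]] > 1)) {
      bad <- c(bad, sprintf("mortality$life_table: %s must lie in [0, 1]", qc))
    }
  }
  for (ec in c("ex_male", "ex_female")) {
    if (any(!is.finite(lt[[ec]])) || any(lt[[ec]] < 0)) {
      bad <- c(bad, sprintf("mortality$life_table: %s must be >= 0", ec))
    } else if (any(diff(lt[[ec]]) > 1e-9)) {
      bad <- c(bad, sprintf("mortality$life_table: %s must be non-increasing in age", ec))
    }
  }
  if (!is.finite(x$ms_hazard_ratio) || x$ms_hazard_ratio <= 0) {
    bad <- c(bad, "mortality$ms_hazard_ratio: must be > 0")
  }
  bad
}

#' Background mortality and life expectancy
#'
#' General-population annual death probabilities and remaining life
#' expectancy by integer age and sex, plus one MS mortality hazard ratio
#' applied uniformly to every living EDSS state (the model's mortality is
#' disability-independent).
#'
#' @param life_table data frame with columns `age` (consecutive integers),
#'   `q_male`, `q_female` (annual death probabilities) and `ex_male`,
#'   `ex_female` (remaining life expectancy in years, non-increasing in age).
#' @param ms_hazard_ratio positive scalar multiplying the background hazard
#'   for all MS patients (default 1.7, a published all-state estimate).
#' @return an object of class `mortality_model`.
#' @export
mortality_model <- function(life_table, ms_hazard_ratio = 1.7) {
  x <- new_mortality_model(life_table, ms_hazard_ratio)
  stop_on_violations(validate_mortality_model(x))
  x
}

# age/sex lookups with explicit range errors
mort_q <- function(mortality, age, sex) {
  lt <- mortality$life_table
  i <- match(age, lt$age)
  if (is.na(i)) stop(sprintf("age %s outside the life table range [%d, %d]", age, min(lt$age), max(lt$age)))
  if (sex == "male") lt$q_male[i] else lt$q_female[i]
}

mort_ex <- function(mortality, age, sex) {
  lt <- mortality$life_table
  i <- match(age, lt$age)
  if (is.na(i)) stop(sprintf("age %s outside the life table range [%d, %d]", age, min(lt$age), max(lt$age)))
  if (sex == "male") lt$ex_male[i] else lt$ex_female[i]
}

new_state_valuation <- function(table) {
  tb <- as.data.frame(table)
  if ("edss" %in% names(tb)) tb$edss <- as.integer(tb$edss)
  for (col in setdiff(names(tb), "edss")) tb[[col]] <- as.numeric(tb[[col]])
  structure(list(table = tb), class = "state_valuation")
}

validate_state_valuation <- function(x) {
  bad <- character()
  tb <- x$table
  miss <- setdiff(VALUATION_COLUMNS, names(tb))
  if (length(miss)) {
    bad <- c(bad, sprintf("valuation: missing column(s) %s", paste(miss, collapse = ", ")))
    return(bad)
  }
  if (nrow(tb) != N_EDSS || !identical(as.integer(tb$edss), EDSS_STATES)) {
    bad <- c(bad, "valuation: must have exactly one row per EDSS 0-9, in order")
    return(bad)
  }
  prop_cols <- c("disability_weight", "employed_fraction", "fulltime_fraction", "invalidity_fraction")
  for (pc in prop_cols) {
    if (any(!is.finite(tb[[pc]])) || any(tb[[pc]] < 0) || any(tb[[pc]] > 1)) {
      bad <- c(bad, sprintf("valuation$%s: must lie in [0, 1]", pc))
    }
  }
  nonneg <- c(DIRECT_COST_CATEGORIES, "informal_care_days",
              "short_term_absence_cost", "long_term_absence_cost")
  for (cc in nonneg) {
    if (any(!is.finite(tb[[cc]])) || any(tb[[cc]] < 0)) {
      bad <- c(bad, sprintf("valuation$%s: must be >= 0", cc))
    }
  }
  bad
}

#' Per-EDSS valuations: disability weights, costs, productivity
#'
#' One row per integer EDSS state 0-9 carrying everything the model attaches
#' to state membership: the disability weight used for YLD, annual direct
#' cost per category (inpatient care, day-care admissions, consultations,
#' tests & investigations, non-DMT medications, community & social services,
#' investments/equipment & aids, informal care), informal-care days per
#' year, employment / full-time / invalidity-pension proportions, and annual
#' short- and long-term productivity-loss costs.
#'
#' @param table data frame with columns `edss`, `disability_weight`, the
#'   eight direct-cost categories, `informal_care_days`,
#'   `employed_fraction`, `fulltime_fraction`, `invalidity_fraction`,
#'   `short_term_absence_cost`, `long_term_absence_cost`.
#' @return an object of class `state_valuation`.
#' @export
state_valuation <- function(table) {
  x <- new_state_valuation(table)
  stop_on_violations(validate_state_valuation(x))
  x
}

new_economic_settings <- function(discount_rate_costs, discount_rate_effects,
                                  annual_relapse_cost, retirement_age,
                                  horizon_years, discontinuation_edss_threshold) {
  structure(
    list(
      discount_rate_costs = as.numeric(discount_rate_costs),
      discount_rate_effects = as.numeric(discount_rate_effects),
      annual_relapse_cost = as.numeric(annual_relapse_cost),
      retirement_age = as.numeric(retirement_age),
      horizon_years = as.integer(horizon_years),
      discontinuation_edss_threshold = as.integer(discontinuation_edss_threshold)
    ),
    class = "economic_settings"
  )
}

validate_economic_settings <- function(x) {
  bad <- character()
  for (f in c("discount_rate_costs", "discount_rate_effects")) {
    if (!is.finite(x[[f]]) || x[[f]] < 0) bad <- c(bad, sprintf("economics$%s: must be >= 0", f))
  }
  if (!is.finite(x$annual_relapse_cost) || x$annual_relapse_cost < 0) {
    bad <- c(bad, "economics$annual_relapse_cost: must be >= 0")
  }
  if (!is.finite(x$retirement_age) || x$retirement_age <= 0) bad <- c(bad, "economics$retirement_age: must be > 0")
  if (is.na(x$horizon_years) || x$horizon_years < 1L) bad <- c(bad, "economics$horizon_years: must be >= 1")
  if (is.na(x$discontinuation_edss_threshold) ||
      x$discontinuation_edss_threshold < 0L || x$discontinuation_edss_threshold > 9L) {
    bad <- c(bad, "economics$discontinuation_edss_threshold: must be an EDSS in 0-9")
  }
  bad
}

#' Economic and run settings
#'
#' @param discount_rate_costs,discount_rate_effects annual discount rates as
#'   fractions (default 0.03 each, i.e. 3% per year).
#' @param annual_relapse_cost societal cost per relapse event (EUR; default
#'   2662).
#' @param retirement_age age in years above which productivity outputs and
#'   indirect costs no longer accrue (default 67).
#' @param horizon_years simulation horizon in annual cycles (default 10).
#' @param discontinuation_edss_threshold DMT is discontinued when EDSS
#'   exceeds this value (default 6: patients at EDSS 7-9 stop treatment).
#' @return an object of class `economic_settings`.
#' @export
economic_settings <- function(discount_rate_costs = 0.03,
                              discount_rate_effects = 0.03,
                              annual_relapse_cost = 2662,
                              retirement_age = 67,
                              horizon_years = 10,
                              discontinuation_edss_threshold = 6) {
  x <- new_economic_settings(discount_rate_costs, discount_rate_effects,
                             annual_relapse_cost, retirement_age,
                             horizon_years, discontinuation_edss_threshold)
  stop_on_violations(validate_economic_settings(x))
  x
}

new_parameter_set <- function(baseline, natural_history, treatments, mortality,
                              valuation, economics) {
  structure(
    list(
      baseline = baseline, natural_history = natural_history,
      treatments = treatments, mortality = mortality,
      valuation = valuation, economics = economics
    ),
    class = "parameter_set"
  )
}

validate_parameter_set <- function(x) {
  bad <- character()
  bad <- c(bad, validate_baseline_cohort(x$baseline))
  bad <- c(bad, validate_natural_history(x$natural_history))
  if (!length(x$treatments)) {
    bad <- c(bad, "treatments: at least one treatment is required")
  } else {
    for (tr in x$treatments) bad <- c(bad, validate_treatment_effect(tr))
    nm <- vapply(x$treatments, `[[`, "", "name")
    if (!identical(unname(nm), names(x$treatments))) {
      bad <- c(bad, "treatments: list names must equal each treatment's own name")
    }
    if (!"none" %in% nm) bad <- c(bad, "treatments: the off-treatment entry 'none' is required")
  }
  bad <- c(bad, validate_mortality_model(x$mortality))
  bad <- c(bad, validate_state_valuation(x$valuation))
  bad <- c(bad, validate_economic_settings(x$economics))
  bad
}

stop_on_violations <- function(bad) {
  if (length(bad)) {
    stop(sprintf("invalid model inputs (%d problem%s):\n  - %s",
                 length(bad), if (length(bad) > 1) "s" else "",
                 paste(bad, collapse = "\n  - ")), call. = FALSE)
  }
  invisible(NULL)
}

#' Assemble a complete, validated parameter set
#'
#' Bundles every model input. All component invariants are re-checked and
#' every violation is reported in a single error. The treatment map must
#' contain the reserved `"none"` entry (used for patients who have
#' discontinued therapy).
#'
#' @param baseline a [baseline_cohort()].
#' @param natural_history a [natural_history()].
#' @param treatments named list of [treatment_effect()] objects; names must
#'   match each effect's own `name`.
#' @param mortality a [mortality_model()].
#' @param valuation a [state_valuation()].
#' @param economics an [economic_settings()].
#' @return an object of class `parameter_set`.
#' @export
parameter_set <- function(baseline, natural_history, treatments, mortality,
                          valuation, economics) {
  if (is.null(names(treatments))) {
    names(treatments) <- vapply(treatments, `[[`, "", "name")
  }
  x <- new_parameter_set(baseline, natural_history, treatments, mortality,
                         valuation, economics)
  stop_on_violations(validate_parameter_set(x))
  x
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  baseline: mean EDSS %.2f, age %.1f, %.0f%% male, cohort %g\n",
              sum(0:6 * x$baseline$edss_distribution), x$baseline$start_age,
              100 * x$baseline$male_fraction, x$baseline$cohort_size))
  cat(sprintf("  treatments: %s\n", paste(names(x$treatments), collapse = ", ")))
  cat(sprintf("  ARR by EDSS: %s\n", paste(format(x$natural_history$arr_by_edss), collapse = " ")))
  cat(sprintf("  mortality: MS hazard ratio %.2f over ages %d-%d\n",
              x$mortality$ms_hazard_ratio, min(x$mortality$life_table$age),
              max(x$mortality$life_table$age)))
  cat(sprintf("  economics: %d-year horizon, %.1f%%/%.1f%% discount, relapse cost %g, retire %g, stop DMT above EDSS %d\n",
              x$economics$horizon_years, 100 * x$economics$discount_rate_costs,
              100 * x$economics$discount_rate_effects, x$economics$annual_relapse_cost,
              x$economics$retirement_age, x$economics$discontinuation_edss_threshold))
  invisible(x)
}
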