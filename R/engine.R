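# Markov cohort engine.
#
# State space: integer EDSS 0-9 crossed with treatment status {on, off} and
# sex {male, female}, plus one absorbing dead state. Cycle length is fixed
# at 1 year (annualised rates, annual costs, annual discounting). Per cycle,
# in order: active-treatment lookup, death (state-independent) competing
# with the EDSS transition conditional on survival, treatment
# discontinuation above the EDSS threshold (irreversible), relapse
# accrual on the resulting state, then ageing by one year.

DMT_STATUS <- c("on", "off")

new_cohort_state <- function(occupancy, dead_mass, current_age, cycle_index) {
  structure(
    list(occupancy = occupancy, dead_mass = dead_mass,
         current_age = current_age, cycle_index = cycle_index),
    class = "cohort_state"
  )
}

empty_occupancy <- function() {
  array(0, dim = c(N_EDSS, 2L, 2L),
        dimnames = list(edss = EDSS_STATES, dmt = DMT_STATUS, sex = SEXES))
}

# total living mass per EDSS state (collapsing treatment status and sex)
living_by_edss <- function(state) {
  apply(state$occupancy, 1L, sum)
}

living_mass <- function(state) sum(state$occupancy)

#' Build the one-cycle transition matrix for one stratum
#'
#' Composes background mortality with the treatment-adjusted EDSS dynamics
#' for a given age, sex and treatment effect. Death is state-independent:
#' the death column equals the age/sex background probability times the MS
#' hazard ratio (capped at 1) for every living state. Conditional on
#' survival, EDSS-worsening probabilities are hazard-adjusted via
#' [apply_hazard_ratio()]; improvement probabilities are untouched and the
#' probability mass freed by reduced worsening is added to "stay".
#'
#' @param nh a [natural_history()].
#' @param effect a [treatment_effect()] (use the `"none"` effect for
#'   off-treatment strata).
#' @param mortality a [mortality_model()].
#' @param age integer age for the life-table lookup.
#' @param sex `"male"` or `"female"`.
#' @return an 11x11 row-stochastic matrix over (EDSS 0-9, dead), with an
#'   absorbing dead row.
#' @export
build_cycle_matrix <- function(nh, effect, mortality, age, sex) {
  sex <- match.arg(sex, SEXES)
  p_death <- min(1, mort_q(mortality, age, sex) * mortality$ms_hazard_ratio)
  hr <- effect$hr_progression
  A <- matrix(0, N_EDSS + 1L, N_EDSS + 1L,
              dimnames = list(c(EDSS_STATES, "dead"), c(EDSS_STATES, "dead")))
  for (i in seq_len(N_EDSS)) {
    row <- nh$transition_matrix[i, ]
    if (hr != 1 && i < N_EDSS) {
      up <- (i + 1L):N_EDSS
      adj <- apply_hazard_ratio(row[up], hr)
      row[i] <- row[i] + sum(row[up]) - sum(adj)
      row[up] <- adj
      if (row[i] < 0) {
        stop(sprintf(
          "hazard ratio %.3g inflates worsening from EDSS %d beyond the available probability mass",
          hr, i - 1L))
      }
    }
    A[i, seq_len(N_EDSS)] <- (1 - p_death) * row
    A[i, N_EDSS + 1L] <- p_death
  }
  A[N_EDSS + 1L, N_EDSS + 1L] <- 1
  A
}

#' Move over-threshold on-treatment mass off treatment
#'
#' Implements DMT discontinuation above the EDSS threshold (default
#' threshold 6, so patients reaching EDSS 7-9 stop therapy, in line with the
#' trial populations). All on-treatment mass in states above the threshold
#' becomes off-treatment; total mass is unchanged and the operation is
#' idempotent. Discontinuation is irreversible: mass that later improves
#' below the threshold stays off treatment.
#'
#' @param state a `cohort_state`.
#' @param threshold integer EDSS; states strictly above it discontinue.
#' @return the updated `cohort_state`.
#' @export
apply_discontinuation <- function(state, threshold) {
  stopifnot(inherits(state, "cohort_state"))
  threshold <- as.integer(threshold)
  if (threshold < 9L) {
    rows <- (threshold + 2L):N_EDSS  # array rows for EDSS threshold+1 .. 9
    state$occupancy[rows, "off", ] <- state$occupancy[rows, "off", ] +
      state$occupancy[rows, "on", ]
    state$occupancy[rows, "on", ] <- 0
  }
  state
}

#' Expected relapses accrued by a cohort state over one year
#'
#' Sums occupancy times the state-specific annualised relapse rate, with the
#' treatment's relapse rate ratio applied to on-treatment mass only. The
#' dead accrue no relapses.
#'
#' @param state a `cohort_state`.
#' @param arr numeric length-10: untreated ARR per EDSS state.
#' @param effect the active [treatment_effect()].
#' @return expected relapse count per patient for one cycle.
#' @export
expected_relapses <- function(state, arr, effect) {
  stopifnot(inherits(state, "cohort_state"), length(arr) == N_EDSS)
  on_mass <- apply(state$occupancy[, "on", , drop = FALSE], 1L, sum)
  off_mass <- apply(state$occupancy[, "off", , drop = FALSE], 1L, sum)
  sum(on_mass * arr) * effect$rr_relapse + sum(off_mass * arr)
}

#' Run one treatment-sequencing scenario
#'
#' Advances the baseline cohort cycle by cycle over the scenario horizon.
#' Cycle 0 is the baseline snapshot: everyone alive, on treatment, at the
#' starting age. Each subsequent cycle looks up the active treatment,
#' builds the per-sex transition matrices at the current integer age (ages
#' are floored for the life-table lookup), takes one matrix step,
#' applies discontinuation, records expected relapses on the resulting
#' state, and ages the cohort by one year. Off-treatment strata evolve
#' under the `"none"` effect and accrue no drug cost downstream.
#'
#' @param params a [parameter_set()].
#' @param scenario a [scenario_spec()]; every referenced treatment must
#'   exist in `params$treatments`.
#' @return an object of class `cohort_trace`: list with `states` (one
#'   `cohort_state` per cycle 0..horizon), `new_deaths` (horizon x 2 matrix
#'   of per-cycle death mass by sex), `expected_relapses` (length horizon),
#'   `active_treatment` (length horizon), and the scenario metadata.
#' @export
run_scenario <- function(params, scenario) {
  stopifnot(inherits(params, "parameter_set"), inherits(scenario, "scenario_spec"))
  h <- scenario$horizon
  missing_trt <- setdiff(unique(scenario$segments$treatment), names(params$treatments))
  if (length(missing_trt)) {
    stop(sprintf("scenario '%s' references unknown treatment(s): %s",
                 scenario$label, paste(missing_trt, collapse = ", ")))
  }

  bl <- params$baseline
  occ <- empty_occupancy()
  occ[1:7, "on", "male"] <- bl$edss_distribution * bl$male_fraction
  occ[1:7, "on", "female"] <- bl$edss_distribution * (1 - bl$male_fraction)

  states <- vector("list", h + 1L)
  states[[1L]] <- new_cohort_state(occ, dead_mass = 0,
                                   current_age = bl$start_age, cycle_index = 0L)
  new_deaths <- matrix(0, nrow = h, ncol = 2L, dimnames = list(NULL, SEXES))
  relapses <- numeric(h)
  active <- character(h)

  none_eff <- params$treatments[["none"]]
  thr <- params$economics$discontinuation_edss_threshold

  cur <- states[[1L]]
  for (t in seq_len(h)) {
    trt <- active_treatment(scenario, t - 1L)
    active[t] <- trt
    eff <- params$treatments[[trt]]
    age_int <- as.integer(floor(cur$current_age))

    nxt <- empty_occupancy()
    for (sex in SEXES) {
      for (status in DMT_STATUS) {
        v <- cur$occupancy[, status, sex]
        if (all(v == 0)) next
        M <- build_cycle_matrix(params$natural_history,
                                if (status == "on") eff else none_eff,
                                params$mortality, age_int, sex)
        out <- as.numeric(c(v, 0) %*% M)
        nxt[, status, sex] <- out[seq_len(N_EDSS)]
        new_deaths[t, sex] <- new_deaths[t, sex] + out[N_EDSS + 1L]
      }
    }
    cur <- new_cohort_state(nxt,
                            dead_mass = cur$dead_mass + sum(new_deaths[t, ]),
                            current_age = cur$current_age + 1,
                            cycle_index = t)
    cur <- apply_discontinuation(cur, thr)
    relapses[t] <- expected_relapses(cur, params$natural_history$arr_by_edss, eff)
    states[[t + 1L]] <- cur
  }

  structure(
    list(states = states, new_deaths = new_deaths,
         expected_relapses = relapses, active_treatment = active,
         scenario = scenario, start_age = bl$start_age, horizon = h),
    class = "cohort_trace"
  )
}

#' Continue a scenario run from a stored cohort state
#'
#' Internal building block used to verify segment-concatenation
#' consistency; advances `state` under a scenario spec as [run_scenario()]
#' does but starting from an arbitrary state.
#' @noRd
continue_scenario <- function(params, scenario, state) {
  h <- scenario$horizon
  none_eff <- params$treatments[["none"]]
  thr <- params$economics$discontinuation_edss_threshold
  states <- vector("list", h + 1L)
  states[[1L]] <- state
  new_deaths <- matrix(0, nrow = h, ncol = 2L, dimnames = list(NULL, SEXES))
  relapses <- numeric(h)
  active <- character(h)
  cur <- state
  for (t in seq_len(h)) {
    trt <- active_treatment(scenario, t - 1L)
    active[t] <- trt
    eff <- params$treatments[[trt]]
    age_int <- as.integer(floor(cur$current_age))
    nxt <- empty_occupancy()
    for (sex in SEXES) {
      for (status in DMT_STATUS) {
        v <- cur$occupancy[, status, sex]
        if (all(v == 0)) next
        M <- build_cycle_matrix(params$natural_history,
                                if (status == "on") eff else none_eff,
                                params$mortality, age_int, sex)
        out <- as.numeric(c(v, 0) %*% M)
        nxt[, status, sex] <- out[seq_len(N_EDSS)]
        new_deaths[t, sex] <- new_deaths[t, sex] + out[N_EDSS + 1L]
      }
    }
    cur <- new_cohort_state(nxt, cur$dead_mass + sum(new_deaths[t, ]),
                            cur$current_age + 1, cur$cycle_index + 1L)
    cur <- apply_discontinuation(cur, thr)
    relapses[t] <- expected_relapses(cur, params$natural_history$arr_by_edss, eff)
    states[[t + 1L]] <- cur
  }
  structure(
    list(states = states, new_deaths = new_deaths,
         expected_relapses = relapses, active_treatment = active,
         scenario = scenario, start_age = state$current_age, horizon = h),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  fin <- x$states[[x$horizon + 1L]]
  cat(sprintf("<cohort_trace> %s\n", x$scenario$label))
  cat(sprintf("  %d annual cycles from age %.1f\n", x$horizon, x$start_age))
  cat(sprintf("  final: %.1f%% alive, mean EDSS %.2f, cumulative relapses %.2f/patient\n",
              100 * living_mass(fin), mean_edss(x, x$horizon),
              sum(x$expected_relapses)))
  invisible(x)
}

#' Tidy per-stratum occupancy of a cohort trace
#'
#' @param x a `cohort_trace`.
#' @param row.names,optional,... ignored (base generic signature).
#' @return data frame with columns `cycle`, `edss`, `treatment_status`,
#'   `sex`, `mass`, plus one `dead` row per cycle (with `edss`,
#'   `treatment_status`, `sex` set to `NA`).
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(x$states, function(s) {
    grid <- expand.grid(edss = EDSS_STATES, treatment_status = DMT_STATUS,
                        sex = SEXES, stringsAsFactors = FALSE)
    grid$cycle <- s$cycle_index
    grid$mass <- as.numeric(s$occupancy)
    dead <- data.frame(edss = NA_integer_, treatment_status = NA_character_,
                       sex = NA_character_, cycle = s$cycle_index,
                       mass = s$dead_mass)
    rbind(grid, dead)
  })
  out <- do.call(rbind, rows)
  out[, c("cycle", "edss", "treatment_status", "sex", "mass")]
}

#' Per-cycle summary of a cohort trace
#'
#' @param trace a `cohort_trace`.
#' @return data frame with one row per cycle 0..horizon: `cycle`, `age`,
#'   `living_mass`, `dead_mass`, `new_deaths`, `expected_relapses`,
#'   `active_treatment`, `mean_edss`. Cycle 0 is the baseline snapshot
#'   (no deaths, relapses, or active treatment recorded).
#' @export
trace_summary <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  h <- trace$horizon
  data.frame(
    cycle = 0:h,
    age = vapply(trace$states, `[[`, 0, "current_age"),
    living_mass = vapply(trace$states, living_mass, 0),
    dead_mass = vapply(trace$states, `[[`, 0, "dead_mass"),
    new_deaths = c(NA, rowSums(trace$new_deaths)),
    expected_relapses = c(NA, trace$expected_relapses),
    active_treatment = c(NA, trace$active_treatment),
    mean_edss = vapply(0:h, function(y) mean_edss(trace, y), 0)
  )
}

#' Plot the mean EDSS trajectory of one trace
#'
#' @param x a `cohort_trace`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cohort_trace <- function(x, ...) {
  y <- vapply(0:x$horizon, function(t) mean_edss(x, t), 0)
  graphics::plot(0:x$horizon, y, type = "b", pch = 16,
                 xlab = "Year", ylab = "Mean EDSS (survivors)",
                 main = x$scenario$label, ...)
  invisible(x)
}
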