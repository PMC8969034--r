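# Independent brute-force oracles for the worked fixture.
#
# The fixture's transition support is confined to EDSS 0-2, so everything
# here is hand-unrolled 4-state (EDSS 0-2 + dead) arithmetic per sex,
# written directly from the model's stated composition rules and sharing no
# code with the engine.

fixture_block_P <- function() {
  rbind(c(0.7, 0.2, 0.1),
        c(0.1, 0.7, 0.2),
        c(0.0, 0.1, 0.9))
}

# hazard-adjust worsening entries (j > i) of the 3x3 block, freed mass to stay
fixture_adjusted_block <- function(hr) {
  P <- fixture_block_P()
  A <- P
  A[1, 2:3] <- 1 - (1 - P[1, 2:3])^hr
  A[1, 1] <- P[1, 1] + sum(P[1, 2:3]) - sum(A[1, 2:3])
  A[2, 3] <- 1 - (1 - P[2, 3])^hr
  A[2, 2] <- P[2, 2] + P[2, 3] - A[2, 3]
  A
}

# Hand-unrolled run of the worked fixture under a per-cycle treatment
# schedule (character vector of treatment names, length = horizon).
# Everyone starts on treatment; the fixture never reaches EDSS > 6, so no
# discontinuation occurs and all living mass stays "on".
# Returns per-cycle occupancy (cycle 0..h), deaths and relapses by cycle.
oracle_fixture_run <- function(fx, schedule) {
  h <- length(schedule)
  q <- c(male = 0.02 * 2, female = 0.01 * 2)  # background q times MS HR 2
  arr <- c(0.5, 0.4, 0.3)
  occ <- list(
    male = c(0.5, 0.3, 0.2) * 0.5,
    female = c(0.5, 0.3, 0.2) * 0.5
  )
  occ_by_cycle <- vector("list", h + 1L)
  occ_by_cycle[[1L]] <- occ
  deaths <- matrix(0, h, 2, dimnames = list(NULL, c("male", "female")))
  relapses <- numeric(h)
  for (t in seq_len(h)) {
    eff <- fx$treatments[[schedule[t]]]
    A <- fixture_adjusted_block(eff$hr_progression)
    for (sex in c("male", "female")) {
      v <- occ[[sex]]
      deaths[t, sex] <- sum(v) * q[sex]
      occ[[sex]] <- as.numeric((v * (1 - q[sex])) %*% A)
    }
    relapses[t] <- (sum(occ$male * arr) + sum(occ$female * arr)) * eff$rr_relapse
    occ_by_cycle[[t + 1L]] <- occ
  }
  list(occ = occ_by_cycle, deaths = deaths, relapses = relapses)
}

# living mass by EDSS 0-2 at a given cycle of an oracle run
oracle_living <- function(orun, cycle) {
  orun$occ[[cycle + 1L]]$male + orun$occ[[cycle + 1L]]$female
}

# extract engine-trace living mass over EDSS 0-2 for comparison
trace_living_012 <- function(trace, cycle) {
  st <- trace$states[[cycle + 1L]]
  unname(apply(st$occupancy, 1L, sum)[1:3])
}

# brute-force discounted YLL for an oracle run (ex 30 male / 35 female)
oracle_yll <- function(orun, rate) {
  ex <- c(male = 30, female = 35)
  h <- nrow(orun$deaths)
  total <- 0
  for (t in seq_len(h)) {
    for (sex in c("male", "female")) {
      total <- total + orun$deaths[t, sex] * ex[[sex]] * (1 + rate)^(-(t - 1))
    }
  }
  unname(total)
}

# brute-force discounted YLD (weights 0, 0.1, 0.2 on EDSS 0-2),
# start-of-cycle membership
oracle_yld <- function(orun, rate) {
  w <- c(0, 0.1, 0.2)
  h <- length(orun$occ) - 1L
  sum(vapply(seq_len(h), function(t) {
    sum(oracle_living(orun, t - 1L) * w) * (1 + rate)^(-(t - 1))
  }, 0))
}

# brute-force discounted state costs per category for the fixture
# (per-EDSS unit costs are linear in EDSS with round coefficients)
oracle_state_costs <- function(orun, rate, start_age = 40, retirement_age = 67) {
  e <- 0:2
  unit <- list(
    inpatient_care = 1000 * e, day_care = 100 * e, consultations = 100 + 100 * e,
    tests_investigations = rep(50, 3), medications = 100 * e,
    community_social_services = 50 * e, investments_equipment_aids = 50 * e,
    informal_care = 500 * e,
    short_term_absence = 500 - 50 * e, long_term_absence = 1000 * e
  )
  h <- length(orun$occ) - 1L
  out <- vapply(names(unit), function(nm) {
    sum(vapply(seq_len(h), function(t) {
      if (nm %in% c("short_term_absence", "long_term_absence") &&
          start_age + (t - 1) >= retirement_age) return(0)
      sum(oracle_living(orun, t - 1L) * unit[[nm]]) * (1 + rate)^(-(t - 1))
    }, 0))
  }, 0)
  out
}

# brute-force discounted DMT costs: on-treatment mass (everyone living)
# at start of cycle x price; year-1 tier in the first cycle of each
# contiguous run of a drug
oracle_dmt_costs <- function(fx, orun, schedule, rate) {
  h <- length(schedule)
  total <- 0
  for (t in seq_len(h)) {
    eff <- fx$treatments[[schedule[t]]]
    first_year <- t == 1L || schedule[t] != schedule[t - 1L]
    price <- if (first_year) eff$annual_drug_cost_year1 else eff$annual_drug_cost_subsequent
    total <- total + sum(oracle_living(orun, t - 1L)) * price * (1 + rate)^(-(t - 1))
  }
  total
}

oracle_relapse_costs <- function(orun, unit_cost, rate) {
  h <- length(orun$relapses)
  sum(orun$relapses * unit_cost * (1 + rate)^(-(seq_len(h) - 1)))
}

# uniform-treatment scenario helper
one_drug_scenario <- function(name, horizon = 10) {
  scenario_spec(paste0(name, " only"),
                data.frame(treatment = name, duration = horizon), horizon)
}
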