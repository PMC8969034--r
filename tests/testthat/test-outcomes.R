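# A trace whose living mass is parked at chosen EDSS states: run the worked
# fixture, then overwrite occupancy (outcome functions only read the trace).
parked_trace <- function(edss_mass, dead = 0, horizon = 10) {
  fx <- generate_worked_fixture()
  tr <- run_scenario(fx, one_drug_scenario("OMB", horizon))
  for (t in 0:horizon) {
    occ <- tr$states[[t + 1L]]$occupancy
    occ[, , ] <- 0
    for (nm in names(edss_mass)) {
      occ[as.integer(nm) + 1L, "on", "female"] <- edss_mass[[nm]]
    }
    tr$states[[t + 1L]]$occupancy <- occ
    tr$states[[t + 1L]]$dead_mass <- dead
  }
  tr
}

test_that("band shares aggregate, normalise and decompose as defined", {
  tr <- parked_trace(c("2" = 1))
  s <- edss_band_shares(tr)
  expect_equal(unname(s["mild"]), 1)
  expect_equal(unname(s[c("walking_aid", "wheelchair", "bedridden")]), rep(0, 3))

  # survivor normalisation with dead mass present
  tr2 <- parked_trace(c("1" = 0.3, "5" = 0.2, "7" = 0.1, "9" = 0.1), dead = 0.3)
  s2 <- edss_band_shares(tr2)
  expect_equal(sum(s2[c("mild", "walking_aid", "wheelchair", "bedridden")]), 1,
               tolerance = 1e-12)
  expect_equal(unname(s2["immobile"]),
               unname(s2["wheelchair"] + s2["bedridden"]))
  expect_equal(unname(s2["mild"]), 0.3 / 0.7, tolerance = 1e-12)

  tr3 <- parked_trace(c("1" = 0), dead = 1)
  expect_error(edss_band_shares(tr3), "no survivors")
})

test_that("mean EDSS is the occupancy-weighted survivor mean", {
  expect_equal(mean_edss(parked_trace(c("3" = 0.6), dead = 0.4)), 3)
  uniform <- as.list(rep(0.1, 10))
  names(uniform) <- as.character(0:9)
  expect_equal(mean_edss(parked_trace(uniform)), 4.5, tolerance = 1e-12)

  fx <- generate_worked_fixture()
  tr <- run_scenario(fx, one_drug_scenario("OMB"))
  occ <- apply(tr$states[[11L]]$occupancy, 1, sum)
  expect_equal(mean_edss(tr, 10), sum(0:9 * occ) / sum(occ), tolerance = 1e-14)
})

test_that("years in band count cycles 1..horizon and conserve the horizon", {
  tr <- parked_trace(c("2" = 1))
  expect_equal(years_in_band(tr, 0:3), 10)
  expect_equal(years_in_band(tr, 8:9), 0)

  fx <- generate_worked_fixture()
  trr <- run_scenario(fx, one_drug_scenario("DMF"))
  by_band <- sum(years_in_band(trr, 0:3), years_in_band(trr, 4:6),
                 years_in_band(trr, 7), years_in_band(trr, 8:9))
  years_dead <- sum(vapply(1:10, function(t) trr$states[[t + 1L]]$dead_mass, 0))
  expect_equal(by_band + years_dead, 10, tolerance = 1e-10)
})

test_that("YLL weights deaths by remaining life expectancy, discounted", {
  fx <- generate_worked_fixture()
  tr <- run_scenario(fx, one_drug_scenario("OMB"))

  nodeath <- tr
  nodeath$new_deaths[, ] <- 0
  expect_equal(compute_yll(nodeath, fx$mortality, 0.03), 0)

  # single death parcel: 0.1 at ex = 40, undiscounted -> 4.0
  single <- tr
  single$new_deaths[, ] <- 0
  single$new_deaths[1, "male"] <- 0.1
  m40 <- mortality_model(data.frame(age = 0:110, q_male = 0.01, q_female = 0.01,
                                    ex_male = 40, ex_female = 40), 1)
  expect_equal(compute_yll(single, m40, 0), 4.0)

  orun <- oracle_fixture_run(fx, rep("OMB", 10))
  expect_equal(compute_yll(tr, fx$mortality, 0.03), oracle_yll(orun, 0.03),
               tolerance = 1e-12)
})

test_that("YLD weights living state-years by disability weights, discounted", {
  fx <- generate_worked_fixture()
  tr <- run_scenario(fx, one_drug_scenario("OMB"))
  expect_equal(compute_yld(tr, rep(0, 10), 0.03), 0)

  # full cohort at weight 0.2 for 10 undiscounted years -> 2.0
  parked <- parked_trace(c("2" = 1))
  expect_equal(compute_yld(parked, fx$valuation, 0), 2.0)

  orun <- oracle_fixture_run(fx, rep("OMB", 10))
  expect_equal(compute_yld(tr, fx$valuation, 0.03), oracle_yld(orun, 0.03),
               tolerance = 1e-12)
})

test_that("DALY = YLD + YLL exactly, and relapse totals respond to the rate ratio", {
  fx <- generate_worked_fixture()
  for (drug in c("OMB", "DMF")) {
    tr <- run_scenario(fx, one_drug_scenario(drug))
    rep_ <- outcome_report(tr, fx)
    expect_identical(rep_$daly, rep_$yld + rep_$yll)
  }
  lo <- run_scenario(fx, one_drug_scenario("OMB"))   # rr 0.5
  hi <- run_scenario(fx, one_drug_scenario("GA"))    # rr 0.9
  expect_lt(total_relapses(lo), total_relapses(hi))

  zero <- fx
  zero$natural_history$arr_by_edss <- rep(0, 10)
  expect_equal(total_relapses(run_scenario(zero, one_drug_scenario("OMB"))), 0)
})

test_that("productivity shares and informal care follow the valuation table", {
  fx <- generate_worked_fixture()
  # uniform employment 0.5 across states -> share 0.5 regardless of occupancy
  fx2 <- fx
  fx2$valuation$table$employed_fraction <- rep(0.5, 10)
  tr <- run_scenario(fx2, one_drug_scenario("OMB"))
  prod <- productivity_and_informal_care(tr, fx2$valuation, 67)
  expect_equal(prod$employed, 0.5, tolerance = 1e-12)
  expect_true(prod$working_age)

  # cohort past retirement: shares reported 0 with the flag down
  old <- fx
  old$baseline$start_age <- 70
  tro <- run_scenario(old, one_drug_scenario("OMB"))
  prodo <- productivity_and_informal_care(tro, old$valuation, 67)
  expect_false(prodo$working_age)
  expect_identical(c(prodo$employed, prodo$fulltime, prodo$invalidity), rep(0, 3))

  # informal-care days against the brute-force oracle (10 * EDSS days/state)
  orun <- oracle_fixture_run(fx, rep("OMB", 10))
  manual <- sum(vapply(1:10, function(t) sum(oracle_living(orun, t) * c(0, 10, 20)), 0))
  expect_equal(productivity_and_informal_care(
    run_scenario(fx, one_drug_scenario("OMB")), fx$valuation, 67)$informal_care_days,
    manual, tolerance = 1e-12)
})
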