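test_that("DMT costs price the loading year of each treatment run, discounted", {
  fx <- generate_worked_fixture()
  spec <- scenario_spec("late switch",
                        data.frame(treatment = c("DMF", "OMB"),
                                   duration = c(5L, 5L)), 10)
  tr <- run_scenario(fx, spec)

  zero <- lapply(fx$treatments, function(t) {
    t$annual_drug_cost_year1 <- 0
    t$annual_drug_cost_subsequent <- 0
    t
  })
  expect_equal(dmt_costs(tr, zero, spec, 0.03), 0)

  # flat price, full survival-weighted exposure, undiscounted
  flat <- lapply(fx$treatments, function(t) {
    t$annual_drug_cost_year1 <- 10000
    t$annual_drug_cost_subsequent <- 10000
    t
  })
  on_years <- sum(vapply(1:10, function(t) sum(tr$states[[t]]$occupancy[, "on", ]), 0))
  expect_equal(dmt_costs(tr, flat, spec, 0), 10000 * on_years, tolerance = 1e-9)

  # oracle including the switch: DMF year-1 price in year 0, DMF thereafter,
  # OMB year-1 price in year 5, OMB subsequent price after
  orun <- oracle_fixture_run(fx, c(rep("DMF", 5), rep("OMB", 5)))
  expect_equal(dmt_costs(tr, fx$treatments, spec, 0.03),
               oracle_dmt_costs(fx, orun, c(rep("DMF", 5), rep("OMB", 5)), 0.03),
               tolerance = 1e-10)
})

test_that("state costs accumulate category by category against the oracle", {
  fx <- generate_worked_fixture()
  tr <- run_scenario(fx, one_drug_scenario("OMB"))
  got <- state_cost_accumulation(tr, fx$valuation, 0.03, 67)
  orun <- oracle_fixture_run(fx, rep("OMB", 10))
  want <- oracle_state_costs(orun, 0.03)
  for (nm in names(got$direct)) {
    expect_equal(unname(got$direct[nm]), unname(want[nm]), tolerance = 1e-10,
                 label = nm)
  }
  for (nm in names(got$indirect)) {
    expect_equal(unname(got$indirect[nm]), unname(want[nm]), tolerance = 1e-10,
                 label = nm)
  }

  zeroval <- fx$valuation
  for (cc in setdiff(names(zeroval$table), "edss")) zeroval$table[[cc]] <- 0
  z <- state_cost_accumulation(tr, zeroval, 0.03, 67)
  expect_true(all(c(z$direct, z$indirect) == 0))

  # indirect costs stop at retirement age
  old <- fx
  old$baseline$start_age <- 64
  tro <- run_scenario(old, one_drug_scenario("OMB"))
  part <- state_cost_accumulation(tro, fx$valuation, 0, 67)
  full <- state_cost_accumulation(tro, fx$valuation, 0, 200)
  expect_lt(part$indirect["long_term_absence"], full$indirect["long_term_absence"])
  expect_equal(part$direct, full$direct)
})

test_that("relapse costs are linear in rate and unit cost, with year-0 basis", {
  fx <- generate_worked_fixture()
  tr <- run_scenario(fx, one_drug_scenario("OMB"))
  expect_equal(relapse_costs(tr, 0, 0.03), 0)

  one <- tr
  one$expected_relapses <- c(1, rep(0, 9))   # one relapse in year 0
  expect_equal(relapse_costs(one, 2662, 0.03), 2662)

  doubled <- fx
  doubled$natural_history$arr_by_edss <- 2 * fx$natural_history$arr_by_edss
  tr2 <- run_scenario(doubled, one_drug_scenario("OMB"))
  expect_equal(relapse_costs(tr2, 2662, 0.03), 2 * relapse_costs(tr, 2662, 0.03),
               tolerance = 1e-12)

  orun <- oracle_fixture_run(fx, rep("OMB", 10))
  expect_equal(relapse_costs(tr, 2662, 0.03), oracle_relapse_costs(orun, 2662, 0.03),
               tolerance = 1e-10)
})

test_that("the cost report satisfies its accounting identities on random inputs", {
  set.seed(99)
  for (k in 1:20) {
    direct <- stats::setNames(runif(8, 0, 5000), mscca:::DIRECT_COST_CATEGORIES)
    indirect <- stats::setNames(runif(2, 0, 5000), mscca:::INDIRECT_COST_CATEGORIES)
    dmt <- runif(1, 0, 2e5)
    rel <- runif(1, 0, 1e4)
    cr <- build_cost_report(dmt, list(direct = direct, indirect = indirect), rel)
    expect_equal(cr$direct_subtotal, dmt + sum(direct), tolerance = 1e-12)
    expect_equal(cr$indirect_subtotal, sum(indirect), tolerance = 1e-12)
    expect_equal(cr$total, cr$direct_plus_indirect + cr$relapse_costs)
    expect_equal(sum(cr$shares$direct), 100, tolerance = 1e-9)
    expect_equal(sum(cr$shares$indirect), 100, tolerance = 1e-9)
    expect_equal(cr$shares$direct_subtotal + cr$shares$indirect_subtotal, 100,
                 tolerance = 1e-9)
    expect_equal(cr$shares$relapse,
                 100 * rel / (dmt + sum(direct) + sum(indirect)), tolerance = 1e-12)
  }
  expect_error(build_cost_report(1, list(direct = 1:3, indirect = 1:2), 1),
               "categories")
})

test_that("every nonzero cost aggregate strictly decreases in the discount rate", {
  fx <- generate_worked_fixture()
  tr <- run_scenario(fx, one_drug_scenario("OMB"))
  for (rates in list(c(0, 0.03), c(0.03, 0.1))) {
    lo <- rates[1]; hi <- rates[2]
    expect_gt(dmt_costs(tr, fx$treatments, tr$scenario, lo),
              dmt_costs(tr, fx$treatments, tr$scenario, hi))
    a <- state_cost_accumulation(tr, fx$valuation, lo, 67)
    b <- state_cost_accumulation(tr, fx$valuation, hi, 67)
    nz <- c(a$direct, a$indirect) > 0
    expect_true(all(c(b$direct, b$indirect)[nz] < c(a$direct, a$indirect)[nz]))
    expect_gt(relapse_costs(tr, 2662, lo), relapse_costs(tr, 2662, hi))
  }
})
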