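make_nh_stay_up <- function(p_stay, p_up) {
  # every state worsens one step with probability p_up (last state stays)
  m <- diag(10) * 0
  for (i in 1:9) {
    m[i, i] <- p_stay
    m[i, i + 1] <- p_up
  }
  m[10, 10] <- 1
  natural_history(m, rep(0, 10))
}

flat_mortality <- function(q_male, q_female, hr = 1, ex = 40) {
  mortality_model(data.frame(age = 0:110, q_male = q_male, q_female = q_female,
                             ex_male = ex, ex_female = ex), hr)
}

test_that("cycle matrix equals natural history when hr = 1 and mortality = 0", {
  fx <- generate_worked_fixture()
  A <- build_cycle_matrix(fx$natural_history, treatment_effect("none"),
                          flat_mortality(0, 0), age = 40, sex = "female")
  expect_equal(unname(A[1:10, 1:10]), unname(fx$natural_history$transition_matrix),
               tolerance = 1e-15)
  expect_identical(unname(A[11, ]), c(rep(0, 10), 1))  # absorbing death
  expect_identical(unname(A[1:10, 11]), rep(0, 10))
})

test_that("death and hazard adjustment compose in the declared order", {
  # p_worsen = 0.2, hr = 0.5, p_death = 0.1:
  # worsening entry = (1 - 0.1) * (1 - 0.8^0.5)
  nh <- make_nh_stay_up(0.8, 0.2)
  eff <- treatment_effect("OMB", hr_progression = 0.5)
  A <- build_cycle_matrix(nh, eff, flat_mortality(0.1, 0.1), 40, "male")
  expect_equal(unname(A[1, 2]), 0.9 * (1 - 0.8^0.5), tolerance = 1e-15)
  expect_equal(unname(A[1, 2]), 0.0950155281000757, tolerance = 1e-12)
  expect_equal(unname(A[1, 11]), 0.1)
  # freed worsening mass lands on "stay"
  expect_equal(unname(A[1, 1]), 0.9 * (0.8 + 0.2 - (1 - 0.8^0.5)), tolerance = 1e-15)
})

test_that("cycle matrices are row-stochastic for random inputs", {
  for (seed in 1:40) {
    ps <- generate_parameter_set(synthetic_config(seed = seed))
    for (trt in c("OMB", "DMF", "GA", "none")) {
      A <- build_cycle_matrix(ps$natural_history, ps$treatments[[trt]],
                              ps$mortality, age = 10 + 2 * seed, sex = "female")
      expect_equal(unname(rowSums(A)), rep(1, 11), tolerance = 1e-12)
      expect_true(all(A >= 0))
    }
  }
})

test_that("life-table range and degenerate hazard ratios are rejected", {
  fx <- generate_worked_fixture()
  expect_error(build_cycle_matrix(fx$natural_history, fx$treatments$OMB,
                                  fx$mortality, age = 500, sex = "male"),
               "life table")
  # an enormous hr would need more worsening mass than the row holds:
  # two worsening destinations saturating near 1 each overdraw the row
  m <- diag(10) * 0
  m[1, 1:3] <- c(0.2, 0.4, 0.4)
  for (i in 2:9) m[i, i] <- 1
  m[10, 10] <- 1
  nh <- natural_history(m, rep(0, 10))
  expect_error(build_cycle_matrix(nh, treatment_effect("X", hr_progression = 50),
                                  flat_mortality(0, 0), 40, "male"),
               "beyond the available probability mass")
})

test_that("discontinuation moves exactly the over-threshold on-DMT mass and is idempotent", {
  fx <- generate_worked_fixture()
  tr <- run_scenario(fx, one_drug_scenario("OMB"))
  st <- tr$states[[3L]]
  # everything at EDSS <= 6: a no-op
  expect_identical(apply_discontinuation(st, 6)$occupancy, st$occupancy)

  st$occupancy[8, "on", "female"] <- 0.1  # EDSS 7 on treatment
  moved <- apply_discontinuation(st, 6)
  expect_identical(unname(moved$occupancy[8, "on", "female"]), 0)
  expect_identical(unname(moved$occupancy[8, "off", "female"]), 0.1)
  expect_equal(sum(moved$occupancy), sum(st$occupancy))
  expect_identical(apply_discontinuation(moved, 6), moved)
})

test_that("expected relapses are occupancy x ARR x treatment ratio", {
  fx <- generate_worked_fixture()
  tr <- run_scenario(fx, one_drug_scenario("OMB"))
  st <- tr$states[[1L]]

  expect_identical(expected_relapses(st, rep(0, 10), fx$treatments$OMB), 0)

  one <- st
  one$occupancy[, , ] <- 0
  one$occupancy[1, "on", "female"] <- 1  # all mass at EDSS 0, arr 0.7, rr 0.5
  expect_equal(expected_relapses(one, rep(0.7, 10),
                                 treatment_effect("T", 1, 0.5)), 0.35)

  # brute-force per-stratum sum on a mid-run state
  st5 <- tr$states[[6L]]
  manual <- 0
  for (sex in c("male", "female")) {
    manual <- manual + sum(st5$occupancy[, "on", sex] *
                             fx$natural_history$arr_by_edss) * 0.5
    manual <- manual + sum(st5$occupancy[, "off", sex] *
                             fx$natural_history$arr_by_edss)
  }
  expect_equal(expected_relapses(st5, fx$natural_history$arr_by_edss,
                                 fx$treatments$OMB), manual, tolerance = 1e-15)
})

test_that("a zero-length horizon returns just the baseline state", {
  fx <- generate_worked_fixture()
  # horizon-0 is disallowed by scenario_spec (durations must be positive),
  # so the smallest run is one cycle; its cycle-0 state is the baseline
  tr <- run_scenario(fx, one_drug_scenario("OMB", 1))
  st0 <- tr$states[[1L]]
  expect_equal(sum(st0$occupancy), 1)
  expect_identical(st0$dead_mass, 0)
  expect_identical(unname(st0$occupancy[1:3, "on", "male"]),
                   c(0.5, 0.3, 0.2) * 0.5)
  expect_true(all(st0$occupancy[, "off", ] == 0))
})

test_that("the engine trace matches the hand-unrolled fixture oracle", {
  fx <- generate_worked_fixture()
  schedule <- c(rep("DMF", 5), rep("OMB", 5))
  spec <- scenario_spec("late switch",
                        data.frame(treatment = c("DMF", "OMB"),
                                   duration = c(5L, 5L)), 10)
  tr <- run_scenario(fx, spec)
  orun <- oracle_fixture_run(fx, schedule)
  for (t in 0:10) {
    expect_equal(trace_living_012(tr, t), oracle_living(orun, t), tolerance = 1e-12)
    # no mass ever escapes EDSS 0-2 in the fixture
    expect_equal(sum(apply(tr$states[[t + 1L]]$occupancy, 1, sum)[4:10]), 0)
  }
  expect_equal(unname(rowSums(tr$new_deaths)), unname(rowSums(orun$deaths)),
               tolerance = 1e-12)
  expect_equal(tr$expected_relapses, orun$relapses, tolerance = 1e-12)
})

test_that("indistinguishable treatments produce identical traces across scenarios", {
  fx <- generate_worked_fixture()
  for (nm in c("OMB", "DMF", "GA")) {
    fx$treatments[[nm]]$hr_progression <- 1
    fx$treatments[[nm]]$rr_relapse <- 1
    fx$treatments[[nm]]$annual_drug_cost_year1 <- 5000
    fx$treatments[[nm]]$annual_drug_cost_subsequent <- 5000
  }
  traces <- lapply(builtin_scenarios("DMF"), function(s) run_scenario(fx, s))
  for (j in 2:4) {
    for (t in 0:10) {
      expect_identical(traces[[j]]$states[[t + 1L]]$occupancy,
                       traces[[1L]]$states[[t + 1L]]$occupancy)
    }
    expect_identical(traces[[j]]$expected_relapses, traces[[1L]]$expected_relapses)
  }
})

test_that("mass is conserved, death is monotone, and zero mortality kills no one", {
  for (seed in 1:10) {
    ps <- generate_parameter_set(synthetic_config(seed = seed))
    for (sc in builtin_scenarios("DMF")) {
      tr <- run_scenario(ps, sc)
      for (st in tr$states) {
        expect_equal(sum(st$occupancy) + st$dead_mass, 1, tolerance = 1e-10)
      }
      dm <- vapply(tr$states, `[[`, 0, "dead_mass")
      expect_true(all(diff(dm) >= -1e-15))
    }
  }
  ps0 <- generate_parameter_set(synthetic_config(seed = 3))
  ps0$mortality <- flat_mortality(0, 0)
  tr0 <- run_scenario(ps0, builtin_scenarios("GA")[["5/5"]])
  expect_identical(vapply(tr0$states, `[[`, 0, "dead_mass"), rep(0, 11))
})

test_that("a lower progression hazard stochastically dominates at every cutoff and cycle", {
  ps <- generate_parameter_set(synthetic_config(seed = 11))
  better <- ps
  better$treatments$DMF$hr_progression <- 0.5
  worse <- ps
  worse$treatments$DMF$hr_progression <- 0.9
  spec <- one_drug_scenario("DMF")
  trb <- run_scenario(better, spec)
  trw <- run_scenario(worse, spec)
  for (t in 0:10) {
    ob <- apply(trb$states[[t + 1L]]$occupancy, 1, sum)
    ow <- apply(trw$states[[t + 1L]]$occupancy, 1, sum)
    for (cut in 1:9) {
      expect_lte(sum(ob[(cut + 1):10]), sum(ow[(cut + 1):10]) + 1e-12)
    }
  }
})

test_that("mean EDSS at year 10 worsens monotonically with later switching", {
  for (seed in c(2, 21)) {
    ps <- generate_parameter_set(synthetic_config(seed = seed))
    for (cmp in c("DMF", "GA")) {
      final <- vapply(builtin_scenarios(cmp),
                      function(s) mean_edss(run_scenario(ps, s)), 0)
      expect_true(all(diff(final) >= -1e-12),
                  label = sprintf("seed %d vs %s: %s", seed, cmp,
                                  paste(round(final, 3), collapse = " <= ")))
    }
  }
})
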