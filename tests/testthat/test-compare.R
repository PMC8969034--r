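test_that("a comparison bundle writes every declared file deterministically", {
  ps <- generate_parameter_set(synthetic_config(seed = 4))
  cmp <- cca_compare(ps, "DMF")
  d1 <- withr::local_tempdir()
  man <- write_cca(cmp, d1, params = ps)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  for (f in man$files) expect_true(file.exists(file.path(d1, f)), label = f)
  expect_true(all(c("outcomes.csv", "costs.csv", "cost_shares.csv",
                    "mean_edss_by_year.csv", "years_in_band.csv") %in% man$files))
  expect_length(man$scenarios, 4)

  # rerun with the same inputs: byte-identical numeric outputs
  d2 <- withr::local_tempdir()
  write_cca(cca_compare(generate_parameter_set(synthetic_config(seed = 4)), "DMF"),
            d2, params = ps)
  for (f in man$files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("delta columns equal independently recomputed scenario differences", {
  ps <- generate_parameter_set(synthetic_config(seed = 4))
  cmp <- cca_compare(ps, "DMF")
  sc <- builtin_scenarios("DMF")
  ref <- outcome_report(run_scenario(ps, sc[["10/0"]]), ps)
  late <- outcome_report(run_scenario(ps, sc[["5/5"]]), ps)

  row <- function(df, m) df[df$metric == m, ]
  expect_equal(row(cmp$outcomes, "relapses")$`delta_5/5`,
               late$total_relapses - ref$total_relapses, tolerance = 1e-12)
  expect_equal(row(cmp$outcomes, "mild_pct")$`delta_5/5`,
               100 * (late$band_shares[["mild"]] - ref$band_shares[["mild"]]),
               tolerance = 1e-12)
  expect_equal(row(cmp$outcomes, "dalys")$`delta_5/5`,
               late$daly - ref$daly, tolerance = 1e-12)

  crow <- function(m) cmp$costs[cmp$costs$category == m, ]
  cref <- cost_report(run_scenario(ps, sc[["10/0"]]), ps)
  clate <- cost_report(run_scenario(ps, sc[["5/5"]]), ps)
  expect_equal(crow("total")$`delta_pct_5/5`,
               100 * (clate$total - cref$total) / cref$total, tolerance = 1e-12)
})

test_that("run_sensitivity writes tornado files and honours an empty factor list", {
  fx <- generate_worked_fixture()
  d <- withr::local_tempdir()
  tor <- run_sensitivity(fx, d, comparator_name = "DMF",
                         factors = c("omb_cost_subsequent", "relapse_cost"))
  expect_true(file.exists(file.path(d, "tornado.csv")))
  expect_true(file.exists(file.path(d, "tornado.json")))
  expect_identical(nrow(read.csv(file.path(d, "tornado.csv"))), 2L)

  d0 <- withr::local_tempdir()
  tor0 <- run_sensitivity(fx, d0, comparator_name = "DMF", factors = character())
  expect_identical(nrow(tor0), 0L)
  expect_true(file.exists(file.path(d0, "tornado.csv")))
})

test_that("print and plot methods run cleanly", {
  fx <- generate_worked_fixture()
  tr <- run_scenario(fx, one_drug_scenario("OMB"))
  expect_output(print(tr), "cohort_trace")
  expect_output(print(outcome_report(tr, fx)), "DALYs")
  expect_output(print(cost_report(tr, fx)), "Total costs")
  expect_output(print(fx), "parameter_set")
  cmp <- cca_compare(generate_parameter_set(synthetic_config(seed = 9)), "GA")
  expect_output(print(cmp), "cca_comparison")
  expect_output(summary(cmp), "Cost shares")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(tr))
  expect_silent(plot(cmp))
  tor <- univariate_sensitivity(fx, one_drug_scenario("OMB"),
                                one_drug_scenario("DMF"),
                                factors = c("omb_cost_subsequent", "relapse_cost"))
  expect_silent(plot(tor))
})

test_that("tidy trace export conserves mass cycle by cycle", {
  fx <- generate_worked_fixture()
  tr <- run_scenario(fx, one_drug_scenario("DMF"))
  df <- as.data.frame(tr)
  expect_named(df, c("cycle", "edss", "treatment_status", "sex", "mass"))
  tot <- as.numeric(tapply(df$mass, df$cycle, sum))
  expect_equal(tot, rep(1, 11), tolerance = 1e-10)
  sm <- trace_summary(tr)
  expect_identical(nrow(sm), 11L)
  expect_equal(sm$living_mass + sm$dead_mass, rep(1, 11), tolerance = 1e-10)
})
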