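test_that("the two-age toy model reproduces hand-composed streams", {
  toy <- toy_inputs()
  gp <- project_scenario(scenario_gp(), toy$lt, toy$profiles, toy$params,
                         mgmt = toy$mgmt)
  # per working age: direct 5,000 + VAT 0.2 * 5,000 = 6,000 of gross tax
  expect_equal(gp$direct_tax[gp$age %in% 30:31], c(5000, 5000))
  expect_equal(gp$indirect_tax[gp$age %in% 30:31], c(1000, 1000))
  sgp <- fiscal_summary(gp)
  expect_equal(sgp$gross_tax, 12000)
  expect_equal(sgp$lifetime_earnings, 20000)
  expect_equal(sgp$work_years, 3)  # ages 29..31 at activity 1
  al <- project_scenario(scenario_al_w(), toy$lt, toy$profiles, toy$params,
                         mgmt = toy$mgmt, attack_cost = 0)
  expect_true(all(al$earnings[al$age >= 30] == 0))
  expect_equal(fiscal_summary(al)$gross_tax, 0)
})

test_that("comparator ledger composition: background disability, GP health, work to retirement", {
  led <- ref_ledgers$gp
  params <- ref_params
  expect_true(all(led$earnings[led$age %in% 18:64] > 0))
  expect_true(all(led$earnings[led$age >= 65] == 0))
  bg <- fx$profiles$disability_rate[match(30:64, fx$profiles$age)]
  expect_equal(led$disability[led$age %in% 30:64] /
                 (params$disability_annual *
                    (1 + params$transfer_inflation)^(30:64 - 30)), bg)
  expect_true(all(led$health_cost[led$age >= 30] > 0))
  expect_true(all(led$health_cost[led$age < 30] == 0))
})

test_that("a lifelong-attack patient never works from onset and is fully disabled", {
  led <- ref_ledgers$al_w
  expect_true(all(led$earnings[led$age >= 30] == 0))
  expect_true(all(led$earnings[led$age %in% 18:29] ==
                    ref_ledgers$gp$earnings[led$age %in% 18:29]))
  expect_equal(led$disability[led$age %in% 30:64],
               ref_params$disability_annual *
                 (1 + ref_params$transfer_inflation)^(30:64 - 30))
})

test_that("return to work restores the comparator pattern after recovery", {
  led <- ref_ledgers$a10_plus_w
  gp <- ref_ledgers$gp
  expect_true(all(led$earnings[led$age %in% 30:39] == 0))
  expect_equal(led$earnings[led$age >= 40], gp$earnings[gp$age >= 40])
  expect_equal(led$disability[led$age >= 40], gp$disability[gp$age >= 40])
  expect_error(scenario_spec("bad", able_to_return_to_work = TRUE,
                             post_attack_work_disabled = FALSE,
                             attack_duration_years = Inf),
               class = "ahpfisc_validation_error")
})

test_that("summary additivity holds exactly for every scenario", {
  for (s in ref_summaries) {
    expect_identical(s$sum_government_costs,
                     s$disability_transfers + s$pension_costs + s$health_costs)
  }
  toy <- toy_inputs()
  zero <- fiscal_summary(project_scenario(scenario_gp(), toy$lt,
                                          flat_profiles(0, 0, 0, 0, 29:33),
                                          toy$params, mgmt = toy$mgmt))
  for (f in c("disability_transfers", "pension_costs", "health_costs",
              "sum_government_costs", "lifetime_earnings", "gross_tax",
              "work_years")) {
    expect_equal(zero[[f]], 0)
  }
})

test_that("with no mortality, flat profiles and zero growth every field matches an annuity", {
  params <- fiscal_parameters(wage_growth = 0, transfer_inflation = 0,
                              health_inflation = 0, discount_rate = 0.03)
  lt <- flat_life_table(0)
  pr <- flat_profiles(gross = 40000, activity = 0.8, disability = 0.1,
                      gp_cost = 1500)
  s <- fiscal_summary(project_scenario(scenario_gp(), lt, pr, params))
  ann <- function(from, to) sum(1.03^-(pmax(0, from:to - 30)))
  expect_equal(s$lifetime_earnings, 40000 * 0.8 * ann(18, 64), tolerance = 1e-9)
  expect_equal(s$gross_tax, 0.62633 * s$lifetime_earnings, tolerance = 1e-9)
  expect_equal(s$disability_transfers, 0.1 * 13613 * ann(30, 64),
               tolerance = 1e-9)
  expect_equal(s$pension_costs, 14400 * ann(65, 100), tolerance = 1e-9)
  expect_equal(s$health_costs, 1500 * ann(30, 100), tolerance = 1e-9)
  expect_equal(s$work_years, 0.8 * ann(18, 64), tolerance = 1e-9)
})

test_that("every lifetime total weakly decreases as the discount rate rises", {
  for (r in c(0, 0.03)) {
    lo <- fiscal_summary(project_scenario(
      scenario_a10_w(), fx$life_table, fx$profiles,
      fiscal_parameters(discount_rate = r)))
    hi <- fiscal_summary(project_scenario(
      scenario_a10_w(), fx$life_table, fx$profiles,
      fiscal_parameters(discount_rate = r + 0.02)))
    for (f in c("disability_transfers", "pension_costs", "health_costs",
                "sum_government_costs", "lifetime_earnings", "gross_tax",
                "work_years")) {
      expect_lte(hi[[f]], lo[[f]])
    }
  }
})

test_that("deltas and the net fiscal impact follow the sign conventions", {
  d <- fiscal_delta(ref_summaries$al_w, ref_summaries$gp)
  expect_equal(d$societal_cost,
               ref_summaries$gp$lifetime_earnings -
                 ref_summaries$al_w$lifetime_earnings)
  expect_equal(net_fiscal_impact(d),
               d$sum_government_costs - d$gross_tax)
  zero_d <- fiscal_delta(ref_summaries$gp, ref_summaries$gp)
  expect_equal(net_fiscal_impact(zero_d), 0)
  expect_true(all(abs(unlist(tidy(zero_d)$value)) < 1e-9))
  # hand check: outlays +100, taxes +40 -> net cost 60
  a <- as_fiscal_summary("a", 50, 25, 25, 1000, 640, 10)
  b <- as_fiscal_summary("b", 0, 0, 0, 1000, 600, 10)
  expect_equal(net_fiscal_impact(fiscal_delta(a, b)), 60)
})

test_that("chart data column sums reproduce the delta fields", {
  for (nm in c("al_w", "a10_plus_w")) {
    cd <- annual_chart_data(ref_ledgers[[nm]], ref_ledgers$gp)
    d <- fiscal_delta(ref_summaries[[nm]], ref_summaries$gp)
    expect_equal(sum(cd$tax_difference), d$gross_tax, tolerance = 1e-9)
    expect_equal(sum(cd$disability), d$disability_transfers, tolerance = 1e-9)
    expect_equal(sum(cd$pension), d$pension_costs, tolerance = 1e-9)
    expect_equal(sum(cd$health_cost), d$health_costs, tolerance = 1e-9)
  }
  self <- annual_chart_data(ref_ledgers$gp, ref_ledgers$gp)
  expect_true(all(abs(as.matrix(self[-1])) < 1e-12))
})

test_that("tidy and glance expose the summary fields as tibbles", {
  td <- tidy(ref_summaries$gp)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 7)
  gl <- glance(fiscal_delta(ref_summaries$al_w, ref_summaries$gp))
  expect_true(all(c("societal_cost", "net_fiscal_impact") %in% names(gl)))
  expect_equal(gl$net_fiscal_impact,
               net_fiscal_impact(fiscal_delta(ref_summaries$al_w,
                                              ref_summaries$gp)))
})

test_that("autoplot methods return ggplot objects", {
  cd <- annual_chart_data(ref_ledgers$al_w, ref_ledgers$gp)
  expect_s3_class(ggplot2::autoplot(cd), "ggplot")
  expect_s3_class(ggplot2::autoplot(ref_ledgers$gp), "ggplot")
})
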