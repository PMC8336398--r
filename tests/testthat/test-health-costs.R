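test_that("line costs use the canonical total when present, factors otherwise", {
  tbl <- attack_cost_lines(data.frame(
    resource = c("hemin", "icu", "nothing"),
    pct_receiving = c(1, 0.2, 0),
    units = c(4, 2, 5),
    unit_cost = c(592.10, 179.69, 10),
    canonical_total = c(NA, 69.08, NA)))
  costs <- line_costs(tbl)
  expect_equal(costs$cost[1], 2368.40)  # 4 x 592.10 computed from factors
  expect_equal(costs$cost[2], 69.08)    # canonical overrides 0.2*2*179.69
  expect_equal(costs$cost[3], 0)
})

test_that("episode total is additive, permutation-invariant, and guards inputs", {
  tbl <- attack_cost_lines()
  total <- attack_cost_total(tbl)
  expect_equal(total, sum(line_costs(tbl)$cost))
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_equal(attack_cost_total(attack_cost_lines(shuffled)), total)
  one <- attack_cost_lines(data.frame(resource = "x", pct_receiving = 1,
                                      units = 1, unit_cost = 1,
                                      canonical_total = 100))
  expect_equal(attack_cost_total(one), 100)
  expect_error(attack_cost_total(tbl[0, ]), class = "ahpfisc_validation_error")
  expect_error(attack_cost_lines(data.frame(resource = c("a", "a"),
                                            pct_receiving = 1, units = 1,
                                            unit_cost = 1)),
               class = "ahpfisc_validation_error")
})

test_that("patient health stream composes attack and management components", {
  p0 <- zero_rate_params()
  mgmt <- management_costs()
  s <- patient_health_stream(scenario_al_w(), 6180.83, mgmt, p0)
  # 12 attacks x 6,180.83 + 34,252 recurrent management, every active year
  expect_equal(unique(s$amount[s$age >= 30]), 108421.96)
  expect_true(all(s$amount[s$age < 30] == 0))
  # zero attacks and zero management give a zero stream
  s0 <- patient_health_stream(scenario_spec("none", attacks_per_year = 0),
                              0, management_costs(0, 0, 0, 0), p0)
  expect_true(all(s0$amount == 0))
  # health inflation compounds over model time: x 1.02^10 at age 40
  p1 <- fiscal_parameters(health_inflation = 0.02)
  s1 <- patient_health_stream(scenario_al_w(), 6180.83, mgmt, p1)
  expect_equal(s1$amount[s1$age == 40] / s1$amount[s1$age == 30], 1.2189944,
               tolerance = 1e-7)
})

test_that("after attacks stop the symptomatic management cost continues", {
  p0 <- zero_rate_params()
  mgmt <- management_costs()
  s <- patient_health_stream(scenario_a10_w(), 6180.83, mgmt, p0)
  expect_equal(unique(s$amount[s$age %in% 30:39]), 12 * 6180.83 + 34252)
  expect_equal(unique(s$amount[s$age >= 40]), 20930)
  # fractional duration prorates the boundary year
  sp <- scenario_a10_w()
  sp$attack_duration_years <- 7.5
  sf <- patient_health_stream(sp, 6180.83, mgmt, p0)
  expect_equal(sf$amount[sf$age == 37],
               0.5 * (12 * 6180.83 + 34252) + 0.5 * 20930)
  expect_equal(unique(sf$amount[sf$age >= 38]), 20930)
})

test_that("attack component is linear in the attack rate and dominates the symptomatic floor", {
  p0 <- zero_rate_params()
  mgmt <- management_costs()
  s1 <- patient_health_stream(scenario_al_w(), 6180.83, mgmt, p0)
  sp2 <- scenario_al_w(); sp2$attacks_per_year <- 24
  s2 <- patient_health_stream(sp2, 6180.83, mgmt, p0)
  active <- s1$age >= 30
  expect_equal(s2$amount[active] - mgmt$recurrent,
               2 * (s1$amount[active] - mgmt$recurrent))
  symp <- patient_health_stream(scenario_spec("symp", attacks_per_year = 0,
                                              attack_duration_years = 1e-9),
                                6180.83, mgmt, p0)
  expect_true(all(s1$amount[active] >= symp$amount[active]))
})

test_that("background health stream inflates the profile and guards coverage", {
  p0 <- zero_rate_params()
  s <- gp_health_stream(flat_profiles(gp_cost = 1000), p0)
  expect_true(all(s$amount == 1000))
  # compounding oracle: 2,000 * 1.02^20 at age 50
  p1 <- fiscal_parameters(health_inflation = 0.02)
  s1 <- gp_health_stream(flat_profiles(gp_cost = 2000), p1)
  expect_equal(s1$amount[s1$age == 50], 2971.89, tolerance = 1e-5)
  expect_error(gp_health_stream(flat_profiles(ages = 18:50), p1),
               class = "ahpfisc_range_error")
})

test_that("management cost ordering is enforced", {
  expect_error(management_costs(symptomatic = 100, recurrent = 50),
               class = "ahpfisc_validation_error")
  expect_error(management_costs(asymptomatic = -1),
               class = "ahpfisc_validation_error")
})
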