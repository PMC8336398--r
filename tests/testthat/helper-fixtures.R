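# Shared in-code fixtures: closed flat life tables, flat economic profiles and
# stripped-down parameter sets with all growth rates zero, so expected values
# have closed forms.

flat_life_table <- function(qx = 0, max_age = 100) {
  life_table(tibble::tibble(age = 0:max_age, qx = c(rep(qx, max_age), 1)))
}

flat_profiles <- function(gross = 40000, activity = 1, disability = 0,
                          gp_cost = 1000, ages = 18:100) {
  age_profiles(tibble::tibble(age = ages, gross_earnings = gross,
                              activity_rate = activity,
                              disability_rate = disability,
                              gp_health_cost = gp_cost))
}

# Parameters with every growth/inflation/discount rate zeroed, for additive
# hand arithmetic.
zero_rate_params <- function(...) {
  fiscal_parameters(wage_growth = 0, transfer_inflation = 0,
                    health_inflation = 0, discount_rate = 0, ...)
}

# Two-working-age toy model: earnings of 10,000 at ages 30 and 31 only,
# retirement at 32, wedge 0.5, VAT 0.2, no mortality, no discounting.
toy_inputs <- function() {
  params <- fiscal_parameters(
    tax_wedge = 0.5, vat_rate = 0.2, wage_growth = 0, transfer_inflation = 0,
    health_inflation = 0, discount_rate = 0, pension_annual = 0,
    disability_annual = 0, entry_age = 29, base_age = 30, retirement_age = 32,
    horizon_age = 33)
  profiles <- age_profiles(tibble::tibble(
    age = 29:33,
    gross_earnings = c(0, 10000, 10000, 0, 0),
    activity_rate = 1, disability_rate = 0, gp_health_cost = 0))
  list(params = params, lt = flat_life_table(0), profiles = profiles,
       mgmt = management_costs(0, 0, 0, 0))
}

# The calibrated fixture is deterministic and cached by the package.
fx <- belgian_fixture()
ref_params <- fiscal_parameters()

ref_ledgers <- lapply(ahp_scenarios(), function(s) {
  project_scenario(s, fx$life_table, fx$profiles, ref_params)
})
ref_summaries <- lapply(ref_ledgers, fiscal_summary)
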