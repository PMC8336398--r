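#' Project one scenario into an annual cashflow ledger
#'
#' Composes the per-age nominal streams (earnings, direct and indirect taxes,
#' disability transfers, pension, health costs) implied by a scenario, along
#' with the conditional survival and start-of-year discount weights used to
#' aggregate them. Earnings (and their taxes) accrue over the pre-model work
#' window from workforce entry onward; all government cost streams are
#' counted from the model start age (diagnosis) onward.
#'
#' @param spec A [scenario_spec()].
#' @param life_table A [life_table()].
#' @param profile An [age_profiles()] tibble.
#' @param params A [fiscal_parameters()] object.
#' @param attack_table An [attack_cost_lines()] table used to cost one
#'   hospitalised attack (ignored if `attack_cost` is given).
#' @param mgmt A [management_costs()] set.
#' @param attack_cost Optional direct override of the per-attack cost (EUR).
#' @return A `cashflow_ledger` tibble with one row per age
#'   (`entry_age:horizon_age`) and columns `age`, `earnings`, `direct_tax`,
#'   `indirect_tax`, `disability`, `pension`, `health_cost` (all nominal EUR),
#'   `survival` and `discount`.
#' @examples
#' fx <- belgian_fixture()
#' led <- project_scenario(scenario_gp(), fx$life_table, fx$profiles,
#'                         fiscal_parameters())
#' glance(fiscal_summary(led))
#' @export
project_scenario <- function(spec, life_table, profile, params,
                             attack_table = attack_cost_lines(),
                             mgmt = management_costs(),
                             attack_cost = NULL) {
  ages <- model_ages(params)
  surv <- conditional_survival(life_table, params$base_age, params$horizon_age)
  survival <- surv$survival[match(ages, surv$age)]
  survival[ages < params$base_age] <- 1
  discount <- discount_factors(ages, params$discount_rate, params$base_age)

  work_ages <- scenario_work_ages(spec, params)
  earn <- earnings_stream(profile, params, work_ages)
  dtax <- direct_tax_stream(earn, params$tax_wedge)
  itax <- indirect_tax_stream(earn, dtax, params$vat_rate)
  disab <- disability_stream(scenario_disabled_fraction(spec, profile, params),
                             params)
  pens <- pension_stream(params)

  if (spec$comparator) {
    health <- gp_health_stream(profile, params)
  } else {
    if (is.null(attack_cost)) attack_cost <- attack_cost_total(attack_table)
    health <- patient_health_stream(spec, attack_cost, mgmt, params)
  }
  health$amount[ages < params$base_age] <- 0

  ledger <- tibble(age = as.integer(ages),
                   earnings = earn$amount,
                   direct_tax = dtax$amount,
                   indirect_tax = itax$amount,
                   disability = disab$amount,
                   pension = pens$amount,
                   health_cost = health$amount,
                   survival = survival,
                   discount = discount)
  attr(ledger, "spec") <- spec
  attr(ledger, "params") <- params
  attr(ledger, "work_ages") <- work_ages
  attr(ledger, "activity") <- tibble(age = profile$age,
                                     value = profile$activity_rate)
  class(ledger) <- c("cashflow_ledger", class(ledger))
  ledger
}

weighted_total <- function(ledger, col) {
  sum(ledger[[col]] * ledger$survival * ledger$discount)
}

#' Lifetime fiscal summary of a ledger
#'
#' Aggregates each stream over the lifetime as the survival-weighted,
#' discounted sum of its annual amounts, and computes discounted expected
#' work years over the scenario's work ages. The sum of government costs is
#' exactly the sum of the disability, pension and health totals.
#'
#' @param ledger A ledger from [project_scenario()].
#' @param activity Optional activity schedule (tibble `age`, `value`)
#'   overriding the one recorded on the ledger.
#' @param params Optional [fiscal_parameters()] overriding the recorded ones.
#' @return A `fiscal_summary` object with fields `disability_transfers`,
#'   `pension_costs`, `health_costs`, `sum_government_costs`,
#'   `lifetime_earnings`, `gross_tax` (all EUR) and `work_years`.
#' @export
fiscal_summary <- function(ledger, activity = NULL, params = NULL) {
  params <- params %||% attr(ledger, "params")
  activity <- activity %||% attr(ledger, "activity")
  spec <- attr(ledger, "spec")
  work_ages <- attr(ledger, "work_ages") %||%
    params$entry_age:(params$retirement_age - 1)

  act <- tibble(age = activity$age,
                value = ifelse(activity$age %in% work_ages,
                               activity[["value"]], 0))
  surv <- tibble(age = ledger$age, survival = ledger$survival)
  wy <- if (all(act$value == 0)) 0 else {
    expected_work_years(act, surv, params$discount_rate, params$entry_age,
                        params$retirement_age, params$base_age)
  }

  disability <- weighted_total(ledger, "disability")
  pension <- weighted_total(ledger, "pension")
  health <- weighted_total(ledger, "health_cost")
  out <- list(
    scenario = if (!is.null(spec)) spec$name else NA_character_,
    disability_transfers = disability,
    pension_costs = pension,
    health_costs = health,
    sum_government_costs = disability + pension + health,
    lifetime_earnings = weighted_total(ledger, "earnings"),
    gross_tax = weighted_total(ledger, "direct_tax") +
      weighted_total(ledger, "indirect_tax"),
    work_years = wy
  )
  structure(out, class = "fiscal_summary")
}

summary_fields <- c("disability_transfers", "pension_costs", "health_costs",
                    "sum_government_costs", "lifetime_earnings", "gross_tax",
                    "work_years")

#' Construct a fiscal summary from known lifetime totals
#'
#' Wraps externally given lifetime values (for example a published results
#' table) in the same `fiscal_summary` container the engine produces, so that
#' [fiscal_delta()] and [net_fiscal_impact()] can operate on them.
#'
#' @param scenario Scenario label.
#' @param disability_transfers,pension_costs,health_costs,lifetime_earnings,gross_tax
#'   Lifetime EUR totals.
#' @param work_years Discounted expected work years.
#' @param sum_government_costs Optional; defaults to the sum of the three
#'   government cost components.
#' @return A `fiscal_summary` object.
#' @export
as_fiscal_summary <- function(scenario, disability_transfers, pension_costs,
                              health_costs, lifetime_earnings, gross_tax,
                              work_years, sum_government_costs = NULL) {
  structure(list(
    scenario = scenario,
    disability_transfers = disability_transfers,
    pension_costs = pension_costs,
    health_costs = health_costs,
    sum_government_costs = sum_government_costs %||%
      (disability_transfers + pension_costs + health_costs),
    lifetime_earnings = lifetime_earnings,
    gross_tax = gross_tax,
    work_years = work_years
  ), class = "fiscal_summary")
}

#' Scenario-minus-comparator fiscal differences
#'
#' Fieldwise difference of two summaries plus the societal cost of lost
#' productivity under the human-capital approach (the comparator's lifetime
#' earnings minus the scenario's).
#'
#' @param scenario,gp `fiscal_summary` objects (scenario and comparator).
#' @return A `fiscal_delta` object with the seven summary fields as
#'   differences and `societal_cost`.
#' @export
fiscal_delta <- function(scenario, gp) {
  d <- lapply(summary_fields, function(f) scenario[[f]] - gp[[f]])
  names(d) <- summary_fields
  d$scenario <- paste0(scenario$scenario, " - ", gp$scenario)
  d$societal_cost <- gp$lifetime_earnings - scenario$lifetime_earnings
  structure(d, class = "fiscal_delta")
}

#' Net fiscal impact of a scenario
#'
#' Incremental government outlays plus foregone tax revenue:
#' `delta(sum of government costs) - delta(gross tax)`.
#'
#' @param d A [fiscal_delta()].
#' @return Net lifetime fiscal impact in EUR (positive = net cost to
#'   government).
#' @export
net_fiscal_impact <- function(d) {
  d$sum_government_costs - d$gross_tax
}

#' Per-age fiscal differences for charting
#'
#' Survival-weighted, discounted per-age differences between a scenario and
#' the comparator, by category. Column sums reproduce the corresponding
#' [fiscal_delta()] fields exactly.
#'
#' @param ledger,gp_ledger Aligned ledgers from [project_scenario()].
#' @return An `annual_chart_data` tibble with columns `age`,
#'   `tax_difference`, `disability`, `pension`, `health_cost`.
#' @export
annual_chart_data <- function(ledger, gp_ledger) {
  if (nrow(ledger) != nrow(gp_ledger) || any(ledger$age != gp_ledger$age)) {
    abort("ledgers are not aligned on the same ages",
          class = "ahpfisc_alignment_error")
  }
  w <- function(l, col) l[[col]] * l$survival * l$discount
  out <- tibble(
    age = ledger$age,
    tax_difference = (w(ledger, "direct_tax") + w(ledger, "indirect_tax")) -
      (w(gp_ledger, "direct_tax") + w(gp_ledger, "indirect_tax")),
    disability = w(ledger, "disability") - w(gp_ledger, "disability"),
    pension = w(ledger, "pension") - w(gp_ledger, "pension"),
    health_cost = w(ledger, "health_cost") - w(gp_ledger, "health_cost")
  )
  attr(out, "scenario") <- attr(ledger, "spec")$name
  class(out) <- c("annual_chart_data", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.fiscal_summary <- function(x, ...) {
  tibble(metric = summary_fields,
         value = unlist(x[summary_fields], use.names = FALSE))
}

#' @exportS3Method generics::glance
glance.fiscal_summary <- function(x, ...) {
  as_tibble(c(list(scenario = x$scenario), x[summary_fields]))
}

#' @exportS3Method generics::tidy
tidy.fiscal_delta <- function(x, ...) {
  fields <- c(summary_fields, "societal_cost")
  tibble(metric = fields, value = unlist(x[fields], use.names = FALSE))
}

#' @exportS3Method generics::glance
glance.fiscal_delta <- function(x, ...) {
  as_tibble(c(list(scenario = x$scenario), x[summary_fields],
              list(societal_cost = x$societal_cost,
                   net_fiscal_impact = net_fiscal_impact(x))))
}

#' @export
print.fiscal_summary <- function(x, ...) {
  cat(sprintf("<fiscal_summary: %s>\n", x$scenario))
  print(tidy(x))
  invisible(x)
}

#' @export
print.fiscal_delta <- function(x, ...) {
  cat(sprintf("<fiscal_delta: %s>\n", x$scenario))
  print(tidy(x))
  cat(sprintf("net fiscal impact: %.0f\n", net_fiscal_impact(x)))
  invisible(x)
}
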