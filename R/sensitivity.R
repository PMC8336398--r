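owsa_parameter_names <- c("annual_attacks", "attack_duration_years",
                          "chronic_health_cost", "cost_per_attack",
                          "disability_payment")

# Re-run the projection with one parameter multiplied by m and return the
# requested lifetime output.
owsa_eval <- function(parameter, m, spec, fixture, params, mgmt, attack_cost,
                      output) {
  sp <- spec
  pa <- params
  mg <- mgmt
  ac <- attack_cost
  switch(parameter,
    annual_attacks = { sp$attacks_per_year <- sp$attacks_per_year * m },
    attack_duration_years = {
      sp$attack_duration_years <- sp$attack_duration_years * m
    },
    chronic_health_cost = {
      mg <- management_costs(mg$asymptomatic * m, mg$symptomatic * m,
                             mg$recurrent * m, mg$severe * m)
    },
    cost_per_attack = { ac <- ac * m },
    disability_payment = {
      pa$disability_annual <- pa$disability_annual * m
    },
    abort(sprintf("unknown sensitivity parameter '%s'", parameter),
          class = "ahpfisc_validation_error")
  )
  led <- project_scenario(sp, fixture$life_table, fixture$profiles, pa,
                          mgmt = mg, attack_cost = ac)
  fiscal_summary(led)[[output]]
}

#' One-way sensitivity analysis
#'
#' Re-runs the full projection with each parameter in turn at `(1 - fraction)`
#' and `(1 + fraction)` times its base value, all else fixed, and records the
#' induced range in the chosen lifetime output. The default setup varies the
#' annual number of attacks, the attack-phase duration, the chronic
#' disease-management costs (all severity categories jointly), the cost per
#' hospitalised attack and the annual disability payment, on the ten-year
#' attack scenario without return to work, reporting the lifetime sum of
#' government costs.
#'
#' @param fixture An `ahp_fixture` from [calibrate_fixture()] /
#'   [belgian_fixture()].
#' @param spec Scenario to perturb (default [scenario_a10_w()]).
#' @param params A [fiscal_parameters()] object.
#' @param mgmt A [management_costs()] set.
#' @param attack_cost Base cost of one hospitalised attack (EUR).
#' @param parameters Character vector of parameters to vary (subset of
#'   `r paste(owsa_parameter_names, collapse = ", ")`).
#' @param fraction Relative variation (0.25 = +/-25%).
#' @param output Name of the [fiscal_summary()] field to report.
#' @return A `tornado` tibble with columns `parameter`, `low_output`,
#'   `high_output`, `range` and `base_output`, sorted by descending range
#'   (alphabetical tie-break).
#' @export
owsa <- function(fixture,
                 spec = scenario_a10_w(),
                 params = fiscal_parameters(),
                 mgmt = management_costs(),
                 attack_cost = attack_cost_total(attack_cost_lines()),
                 parameters = owsa_parameter_names,
                 fraction = 0.25,
                 output = "sum_government_costs") {
  if (fraction <= 0 || fraction >= 1) {
    abort("fraction must lie in (0, 1)", class = "ahpfisc_validation_error")
  }
  unknown <- setdiff(parameters, owsa_parameter_names)
  if (length(unknown) > 0) {
    abort(paste0("unknown sensitivity parameter(s): ",
                 paste(unknown, collapse = ", ")),
          class = "ahpfisc_validation_error")
  }
  base <- owsa_eval(parameters[1], 1, spec, fixture, params, mgmt,
                    attack_cost, output)
  rows <- purrr::map_dfr(parameters, function(pname) {
    lo <- owsa_eval(pname, 1 - fraction, spec, fixture, params, mgmt,
                    attack_cost, output)
    hi <- owsa_eval(pname, 1 + fraction, spec, fixture, params, mgmt,
                    attack_cost, output)
    tibble(parameter = pname, low_output = lo, high_output = hi,
           range = abs(hi - lo), base_output = base)
  })
  rows <- arrange(rows, desc(.data$range), .data$parameter)
  attr(rows, "fraction") <- fraction
  attr(rows, "output") <- output
  class(rows) <- c("tornado", class(rows))
  rows
}

#' Ranked tornado table
#'
#' Sorts tornado rows by descending range with alphabetical tie-break, and
#' optionally writes them to CSV.
#'
#' @param rows A `tornado` tibble (or compatible data frame with `parameter`,
#'   `low_output`, `high_output`, `range`).
#' @param path Optional CSV output path.
#' @return The ranked tibble, invisibly if written.
#' @export
tornado_report <- function(rows, path = NULL) {
  if (nrow(rows) == 0) {
    abort("tornado table is empty", class = "ahpfisc_validation_error")
  }
  out <- arrange(as_tibble(rows), desc(.data$range), .data$parameter)
  if (!is.null(path)) {
    readr::write_csv(out, path)
    return(invisible(out))
  }
  out
}
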