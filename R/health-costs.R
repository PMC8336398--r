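#' Resource lines for a hospitalised attack episode
#'
#' The default table micro-costs one hospital-treated porphyria attack in
#' Belgium (2020 EUR): opioid analgesia, four days of hemin, the aggregate
#' cost of hemin adverse events, albumin co-administration, emergency-room and
#' ICU admission, seven hospitalisation days and clinical biology. Each line
#' carries the fraction of attacks using the resource, units per attack, the
#' unit cost, and a `canonical_total`. Where present, the canonical per-line
#' total takes precedence over `pct * units * unit_cost`, because several
#' published unit values are rounded and do not reproduce their own line
#' totals exactly; the factors remain available for user-defined lines.
#'
#' @param lines Optional data frame with columns `resource`, `pct_receiving`,
#'   `units`, `unit_cost`, `canonical_total` to replace the default table.
#' @return An `attack_cost_table` tibble.
#' @examples
#' attack_cost_total(attack_cost_lines())
#' @export
attack_cost_lines <- function(lines = NULL) {
  if (is.null(lines)) {
    lines <- tibble::tribble(
      ~resource,                  ~pct_receiving, ~units, ~unit_cost, ~canonical_total,
      "Opioids (morphine)",       1.00,           18,     0.68,       12.29,
      "Hemin",                    1.00,           4,      592.10,     2368.39,
      "Hemin side effects",       1.00,           NA,     NA,         102.45,
      "Albumin",                  1.00,           4,      29.63,      118.52,
      "Hospital admission, ER",   1.00,           1,      43.69,      43.69,
      "Hospital admission, ICU",  0.20,           2,      179.69,     69.08,
      "Hospitalization days",     1.00,           7,      492.27,     3440.42,
      "Blood test",               1.00,           1,      26.00,      26.00
    )
  }
  x <- as_tibble(lines)
  needed <- c("resource", "pct_receiving", "units", "unit_cost")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("attack cost table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ahpfisc_format_error")
  }
  if (!"canonical_total" %in% names(x)) x$canonical_total <- NA_real_
  if (anyDuplicated(x$resource)) {
    abort("attack cost resource labels must be unique",
          class = "ahpfisc_validation_error")
  }
  if (any(x$pct_receiving < 0 | x$pct_receiving > 1, na.rm = TRUE)) {
    abort("pct_receiving must lie in [0, 1]", class = "ahpfisc_validation_error")
  }
  if (any(c(x$units, x$unit_cost, x$canonical_total) < 0, na.rm = TRUE)) {
    abort("units, unit costs and totals must be non-negative",
          class = "ahpfisc_validation_error")
  }
  class(x) <- c("attack_cost_table", class(x))
  x
}

#' Per-line episode costs
#'
#' @param table An [attack_cost_lines()] table.
#' @return The table with a `cost` column: `canonical_total` where present,
#'   otherwise `pct_receiving * units * unit_cost`.
#' @export
line_costs <- function(table) {
  computed <- table$pct_receiving * table$units * table$unit_cost
  mutate(table, cost = ifelse(is.na(.data$canonical_total),
                              computed, .data$canonical_total))
}

#' Total cost of one hospitalised attack
#'
#' @param table An [attack_cost_lines()] table.
#' @return Total episode cost in EUR (sum of [line_costs()]).
#' @export
attack_cost_total <- function(table) {
  if (nrow(table) == 0) {
    abort("attack cost table is empty", class = "ahpfisc_validation_error")
  }
  sum(line_costs(table)$cost)
}

#' Annual disease-management costs by attack-rate category
#'
#' Annual AHP management and comorbidity-treatment costs per severity
#' category (2020 EUR), excluding attack hospitalisations and social costs.
#'
#' @param asymptomatic,symptomatic,recurrent,severe EUR per year.
#' @return A `management_costs` list.
#' @export
management_costs <- function(asymptomatic = 6192, symptomatic = 20930,
                             recurrent = 34252, severe = 34252) {
  m <- list(asymptomatic = asymptomatic, symptomatic = symptomatic,
            recurrent = recurrent, severe = severe)
  if (any(unlist(m) < 0)) {
    abort("management costs must be non-negative",
          class = "ahpfisc_validation_error")
  }
  if (!(recurrent >= symptomatic && symptomatic >= asymptomatic)) {
    abort("management costs must satisfy recurrent >= symptomatic >= asymptomatic",
          class = "ahpfisc_validation_error")
  }
  structure(m, class = "management_costs")
}

#' Annual health-cost stream for an AHP patient
#'
#' During active attack years the patient incurs `attacks_per_year *
#' attack_cost` in hospitalisation costs plus the recurrent-category annual
#' management cost; after attacks stop, the symptomatic-category management
#' cost continues for life (chronic comorbidities persist; the general
#' population background cost is never added on top). All components inflate
#' at the healthcare-inflation rate over model time. A fractional attack
#' duration prorates the final active year between the active and
#' post-attack amounts.
#'
#' @param spec A [scenario_spec()].
#' @param attack_cost Cost of one hospitalised attack (EUR), e.g.
#'   [attack_cost_total()].
#' @param mgmt A [management_costs()] set.
#' @param params A [fiscal_parameters()] object.
#' @return Stream tibble of annual patient health costs.
#' @export
patient_health_stream <- function(spec, attack_cost, mgmt, params) {
  ages <- model_ages(params)
  infl <- (1 + params$health_inflation)^(ages - params$base_age)
  active_amt <- (spec$attacks_per_year * attack_cost + mgmt$recurrent) * infl
  post_amt <- mgmt$symptomatic * infl
  dur <- spec$attack_duration_years
  yrs_since_onset <- ages - spec$onset_age
  active_share <- pmin(1, pmax(0, dur - yrs_since_onset))
  active_share[yrs_since_onset < 0] <- 0
  post_share <- ifelse(yrs_since_onset < 0, 0, 1 - active_share)
  new_stream(ages, active_share * active_amt + post_share * post_amt)
}

#' Background health-cost stream of the general population
#'
#' Age-specific per-capita health expenditure of non-AHP individuals,
#' inflated at the healthcare-inflation rate over model time.
#'
#' @param profile Age-profile tibble with `age` and `gp_health_cost`.
#' @param params A [fiscal_parameters()] object.
#' @return Stream tibble of annual background health costs.
#' @export
gp_health_stream <- function(profile, params) {
  ages <- model_ages(params)
  cost <- profile$gp_health_cost[match(ages, profile$age)]
  if (any(is.na(cost))) {
    abort(sprintf("profile has no gp_health_cost for age %d",
                  min(ages[is.na(cost)])),
          class = "ahpfisc_range_error")
  }
  infl <- (1 + params$health_inflation)^(ages - params$base_age)
  new_stream(ages, cost * infl)
}
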