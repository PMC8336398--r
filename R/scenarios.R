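#' Define a clinical scenario
#'
#' A scenario describes one life course of a recurrent-attack AHP patient:
#' the age at symptom onset (also the model start), the annual number of
#' hospitalised attacks, how long the attack phase lasts, and how work
#' ability evolves. The general-population comparator is a scenario with
#' `comparator = TRUE`: no attacks, background disability and background
#' health costs.
#'
#' @param name Scenario label.
#' @param onset_age Age at symptom onset.
#' @param attacks_per_year Average annual number of hospitalised attacks.
#' @param attack_duration_years Length of the active attack phase in years
#'   (`Inf` for attacks throughout life); may be fractional, in which case the
#'   final active year is prorated.
#' @param work_disabled_during_attacks If `TRUE`, the patient is fully work
#'   disabled from onset while attacks continue.
#' @param post_attack_work_disabled If `TRUE`, work disability persists for
#'   life after attacks stop (chronic comorbidities).
#' @param able_to_return_to_work If `TRUE`, the patient resumes the
#'   general-population work pattern once attacks stop.
#' @param comparator If `TRUE`, this is the general-population comparator.
#' @return A `scenario_spec` list.
#' @seealso [ahp_scenarios()] for the three built-in patient scenarios.
#' @export
scenario_spec <- function(name,
                          onset_age = 30,
                          attacks_per_year = 12,
                          attack_duration_years = Inf,
                          work_disabled_during_attacks = TRUE,
                          post_attack_work_disabled = TRUE,
                          able_to_return_to_work = FALSE,
                          comparator = FALSE) {
  spec <- list(name = name, onset_age = as.integer(onset_age),
               attacks_per_year = attacks_per_year,
               attack_duration_years = attack_duration_years,
               work_disabled_during_attacks = work_disabled_during_attacks,
               post_attack_work_disabled = post_attack_work_disabled,
               able_to_return_to_work = able_to_return_to_work,
               comparator = comparator)
  if (!comparator) {
    if (attack_duration_years <= 0) {
      abort("attack_duration_years must be positive (or Inf for lifelong)",
            class = "ahpfisc_validation_error")
    }
    if (able_to_return_to_work && is.infinite(attack_duration_years)) {
      abort("a scenario cannot return to work while attacks continue for life",
            class = "ahpfisc_validation_error")
    }
    if (able_to_return_to_work && post_attack_work_disabled) {
      abort("able_to_return_to_work contradicts post_attack_work_disabled",
            class = "ahpfisc_validation_error")
    }
    if (attacks_per_year < 0) {
      abort("attacks_per_year must be non-negative",
            class = "ahpfisc_validation_error")
    }
  }
  structure(spec, class = "scenario_spec")
}

#' @rdname ahp_scenarios
#' @export
scenario_gp <- function() {
  scenario_spec("GP", attacks_per_year = 0, attack_duration_years = Inf,
                work_disabled_during_attacks = FALSE,
                post_attack_work_disabled = FALSE, comparator = TRUE)
}

#' @rdname ahp_scenarios
#' @export
scenario_al_w <- function() {
  scenario_spec("AL-W", attack_duration_years = Inf)
}

#' @rdname ahp_scenarios
#' @export
scenario_a10_w <- function() {
  scenario_spec("A10-W", attack_duration_years = 10)
}

#' @rdname ahp_scenarios
#' @export
scenario_a10_plus_w <- function() {
  scenario_spec("A10+W", attack_duration_years = 10,
                post_attack_work_disabled = FALSE,
                able_to_return_to_work = TRUE)
}

#' Built-in scenarios
#'
#' The general-population comparator and the three patient scenarios of the
#' Belgian reference case, all with onset at 30 and 12 hospitalised attacks
#' per year while active: `AL-W` (attacks throughout life, never works
#' again), `A10-W` (attacks stop at 40, chronic comorbidities keep the
#' patient out of work) and `A10+W` (attacks stop at 40, patient returns to
#' work).
#'
#' @return `ahp_scenarios()` returns a named list of the four
#'   `scenario_spec`s (`gp`, `al_w`, `a10_w`, `a10_plus_w`).
#' @export
ahp_scenarios <- function() {
  list(gp = scenario_gp(), al_w = scenario_al_w(), a10_w = scenario_a10_w(),
       a10_plus_w = scenario_a10_plus_w())
}

# Ages at which the scenario's individual is in the labour force.
scenario_work_ages <- function(spec, params) {
  full <- params$entry_age:(params$retirement_age - 1)
  if (spec$comparator || !spec$work_disabled_during_attacks) return(full)
  pre <- full[full < spec$onset_age]
  if (spec$able_to_return_to_work) {
    recovery <- spec$onset_age + ceiling(spec$attack_duration_years)
    c(pre, full[full >= recovery])
  } else {
    pre
  }
}

# Per-age disabled fraction: 1 during patient work-disabled years, the
# background general-population prevalence otherwise.
scenario_disabled_fraction <- function(spec, profile, params) {
  ages <- model_ages(params)
  background <- profile$disability_rate[match(ages, profile$age)] %na% 0
  value <- background
  if (!spec$comparator && spec$work_disabled_during_attacks) {
    if (spec$post_attack_work_disabled || is.infinite(spec$attack_duration_years)) {
      disabled <- ages >= spec$onset_age
    } else {
      recovery <- spec$onset_age + ceiling(spec$attack_duration_years)
      disabled <- ages >= spec$onset_age & ages < recovery
    }
    value[disabled] <- 1
  }
  tibble(age = ages, value = value)
}
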