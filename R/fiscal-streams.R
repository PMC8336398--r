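model_ages <- function(params) params$entry_age:params$horizon_age

new_stream <- function(ages, amount) tibble(age = as.integer(ages), amount = amount)

check_aligned <- function(a, b, what) {
  if (nrow(a) != nrow(b) || any(a$age != b$age)) {
    abort(sprintf("%s streams are not aligned on the same ages", what),
          class = "ahpfisc_alignment_error")
  }
}

#' Nominal gross-earnings stream
#'
#' Cross-sectional age-specific gross earnings, adjusted for the age-specific
#' economic activity rate, with wage growth compounded over model time
#' (`(1 + wage_growth)^(age - base_age)`, exponent floored at 0 for the
#' pre-model ages). Earnings are zero outside `work_ages` and from
#' `retirement_age` on.
#'
#' @param profile Age-profile tibble with `age`, `gross_earnings` and
#'   `activity_rate` (see [age_profiles()]).
#' @param params A [fiscal_parameters()] object.
#' @param work_ages Integer vector of ages at which the individual is in the
#'   labour force.
#' @return A stream tibble (`age`, `amount` in nominal EUR per year) over the
#'   full model window.
#' @export
earnings_stream <- function(profile, params, work_ages) {
  ages <- model_ages(params)
  work_ages <- intersect(work_ages, ages)
  missing <- setdiff(work_ages, profile$age)
  if (length(missing) > 0) {
    abort(sprintf("profile has no earnings for age %d", min(missing)),
          class = "ahpfisc_range_error")
  }
  idx <- match(ages, profile$age)
  gross <- profile$gross_earnings[idx] %na% 0
  act <- profile$activity_rate[idx] %na% 0
  growth <- (1 + params$wage_growth)^pmax(0, ages - params$base_age)
  amount <- gross * act * growth
  amount[!(ages %in% work_ages) | ages >= params$retirement_age] <- 0
  new_stream(ages, amount)
}

#' Direct-tax stream from the tax wedge
#'
#' Direct taxes (income tax plus social contributions) are the tax wedge times
#' gross earnings.
#'
#' @param earnings Earnings stream from [earnings_stream()].
#' @param tax_wedge Fraction in `[0, 1)`.
#' @return Stream tibble of annual direct tax revenue.
#' @export
direct_tax_stream <- function(earnings, tax_wedge) {
  if (tax_wedge < 0 || tax_wedge >= 1) {
    abort("tax_wedge must lie in [0, 1)", class = "ahpfisc_validation_error")
  }
  new_stream(earnings$age, earnings$amount * tax_wedge)
}

#' Indirect (VAT) tax stream
#'
#' VAT on the full consumption of disposable income (gross earnings minus
#' direct tax); no savings rate is modelled.
#'
#' @param earnings,direct_tax Aligned streams.
#' @param vat_rate VAT rate as a fraction.
#' @return Stream tibble of annual VAT revenue.
#' @export
indirect_tax_stream <- function(earnings, direct_tax, vat_rate) {
  check_aligned(earnings, direct_tax, "earnings and direct-tax")
  new_stream(earnings$age, vat_rate * (earnings$amount - direct_tax$amount))
}

#' Disability-transfer stream
#'
#' The average annual disability benefit, indexed at the transfer-inflation
#' rate over model time, times the fraction of the year spent disabled. Paid
#' only between `base_age` and `retirement_age - 1`: at retirement the benefit
#' is replaced by the pension for everyone.
#'
#' @param disabled_fraction Tibble with `age` and `value` in `[0, 1]`.
#' @param params A [fiscal_parameters()] object.
#' @return Stream tibble of annual disability transfers.
#' @export
disability_stream <- function(disabled_fraction, params) {
  ages <- model_ages(params)
  frac <- disabled_fraction$value[match(ages, disabled_fraction$age)] %na% 0
  if (any(frac < 0 | frac > 1)) {
    abort("disabled fractions must lie in [0, 1]",
          class = "ahpfisc_validation_error")
  }
  idx <- (1 + params$transfer_inflation)^(ages - params$base_age)
  amount <- frac * params$disability_annual * idx
  amount[ages < params$base_age | ages >= params$retirement_age] <- 0
  new_stream(ages, amount)
}

#' Retirement-pension stream
#'
#' The average annual pension, indexed at the transfer-inflation rate, paid
#' from `retirement_age` to the horizon. Identical for every scenario and for
#' the general-population comparator.
#'
#' @param params A [fiscal_parameters()] object.
#' @return Stream tibble of annual pension transfers.
#' @export
pension_stream <- function(params) {
  ages <- model_ages(params)
  idx <- (1 + params$transfer_inflation)^(ages - params$base_age)
  amount <- params$pension_annual * idx
  amount[ages < params$retirement_age] <- 0
  new_stream(ages, amount)
}
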