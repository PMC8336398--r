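#' Fiscal and demographic model parameters
#'
#' Constructs the parameter set driving every stream of the projection. The
#' defaults encode the Belgian reference case: a 52.7% tax wedge, 21% VAT on
#' disposable income (full consumption assumed), 1.3% annual wage growth,
#' 0.62% annual indexation of cash transfers, 2% annual healthcare inflation,
#' a 3% discount rate, a EUR 14,400 average annual retirement pension and a
#' EUR 13,613 average annual disability benefit. The modelled individual
#' enters the workforce at 18, is diagnosed (model start / discounting origin)
#' at 30, retires at 65 and is followed to age 100.
#'
#' @param tax_wedge Fraction of gross earnings collected as direct tax.
#' @param vat_rate VAT rate applied to disposable income.
#' @param wage_growth Annual real wage growth applied over model time.
#' @param transfer_inflation Annual indexation of disability and pension
#'   transfers.
#' @param health_inflation Annual health-cost inflation.
#' @param discount_rate Annual discount rate for all streams.
#' @param pension_annual Average annual retirement pension (EUR).
#' @param disability_annual Average annual disability benefit (EUR).
#' @param retirement_age First retired age (pension starts, work stops).
#' @param entry_age Workforce entry age.
#' @param base_age Model start age: discounting origin and the age survival is
#'   conditioned on.
#' @param horizon_age Last modelled age.
#' @param symptomatic_work_disability Fraction of symptomatic (non-recurrent)
#'   patients unable to work; carried for user-defined scenarios, unused by
#'   the three recurrent-attack scenarios, which assume full work disability.
#' @return A `fiscal_parameters` list.
#' @examples
#' p <- fiscal_parameters()
#' p$tax_wedge + p$vat_rate * (1 - p$tax_wedge)  # combined marginal tax take
#' @export
fiscal_parameters <- function(tax_wedge = 0.527,
                              vat_rate = 0.21,
                              wage_growth = 0.013,
                              transfer_inflation = 0.0062,
                              health_inflation = 0.02,
                              discount_rate = 0.03,
                              pension_annual = 14400,
                              disability_annual = 13613,
                              retirement_age = 65,
                              entry_age = 18,
                              base_age = 30,
                              horizon_age = 100,
                              symptomatic_work_disability = 0.5) {
  p <- list(tax_wedge = tax_wedge, vat_rate = vat_rate,
            wage_growth = wage_growth, transfer_inflation = transfer_inflation,
            health_inflation = health_inflation, discount_rate = discount_rate,
            pension_annual = pension_annual,
            disability_annual = disability_annual,
            retirement_age = as.integer(retirement_age),
            entry_age = as.integer(entry_age),
            base_age = as.integer(base_age),
            horizon_age = as.integer(horizon_age),
            symptomatic_work_disability = symptomatic_work_disability)
  validate_fiscal_parameters(p)
  structure(p, class = "fiscal_parameters")
}

validate_fiscal_parameters <- function(p) {
  rates <- c("tax_wedge", "vat_rate", "wage_growth", "transfer_inflation",
             "health_inflation", "discount_rate")
  for (r in rates) {
    if (p[[r]] < 0 || p[[r]] >= 1) {
      abort(sprintf("%s must lie in [0, 1): got %g", r, p[[r]]),
            class = "ahpfisc_validation_error")
    }
  }
  combined <- p$tax_wedge + p$vat_rate * (1 - p$tax_wedge)
  if (combined >= 1) {
    abort("combined direct + indirect tax rate must be below 1",
          class = "ahpfisc_validation_error")
  }
  if (p$pension_annual < 0 || p$disability_annual < 0) {
    abort("transfer amounts must be non-negative",
          class = "ahpfisc_validation_error")
  }
  if (!(p$entry_age < p$base_age && p$base_age < p$retirement_age &&
        p$retirement_age < p$horizon_age)) {
    abort("ages must satisfy entry < base < retirement < horizon",
          class = "ahpfisc_validation_error")
  }
  invisible(p)
}

#' @export
print.fiscal_parameters <- function(x, ...) {
  cat("<fiscal_parameters>\n")
  cat(sprintf("  tax wedge %.1f%%, VAT %.1f%%, discount %.1f%%\n",
              100 * x$tax_wedge, 100 * x$vat_rate, 100 * x$discount_rate))
  cat(sprintf("  wage growth %.2f%%, transfer indexation %.2f%%, health inflation %.2f%%\n",
              100 * x$wage_growth, 100 * x$transfer_inflation,
              100 * x$health_inflation))
  cat(sprintf("  pension EUR %s/yr, disability EUR %s/yr\n",
              format(x$pension_annual, big.mark = ","),
              format(x$disability_annual, big.mark = ",")))
  cat(sprintf("  ages: entry %d, base %d, retirement %d, horizon %d\n",
              x$entry_age, x$base_age, x$retirement_age, x$horizon_age))
  invisible(x)
}
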