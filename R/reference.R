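#' Published lifetime totals of the Belgian reference analysis
#'
#' The lifetime, mortality-adjusted, 3%-discounted totals reported by the
#' published Belgian recurrent-AHP fiscal analysis that this package's
#' default configuration encodes: one column per scenario (general
#' population, attacks for life without work, attacks for ten years without
#' work, attacks for ten years with return to work). These serve as
#' benchmarking inputs — e.g. for delta arithmetic on published cells and as
#' the calibration surface of the synthetic fixture — not as model output.
#'
#' @return A named list of four [as_fiscal_summary()] objects: `gp`, `al_w`,
#'   `a10_w`, `a10_plus_w`.
#' @examples
#' ref <- belgium_reference()
#' net_fiscal_impact(fiscal_delta(ref$al_w, ref$gp))
#' @export
belgium_reference <- function() {
  list(
    gp = as_fiscal_summary("GP",
      disability_transfers = 40277, pension_costs = 83110,
      health_costs = 70218, lifetime_earnings = 632367, gross_tax = 434722,
      work_years = 25.24, sum_government_costs = 193605),
    al_w = as_fiscal_summary("AL-W",
      disability_transfers = 287519, pension_costs = 83110,
      health_costs = 3100534, lifetime_earnings = 284565, gross_tax = 251535,
      work_years = 11.36, sum_government_costs = 3471163),
    a10_w = as_fiscal_summary("A10-W",
      disability_transfers = 287519, pension_costs = 83110,
      health_costs = 1589502, lifetime_earnings = 284565, gross_tax = 251535,
      work_years = 11.36, sum_government_costs = 1960131),
    a10_plus_w = as_fiscal_summary("A10+W",
      disability_transfers = 108335, pension_costs = 83110,
      health_costs = 1589502, lifetime_earnings = 509141, gross_tax = 369819,
      work_years = 20.88, sum_government_costs = 1780947)
  )
}
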