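#' Parameters of the synthetic country generator
#'
#' Describes a Belgian-like country with closed-form age laws: a
#' Gompertz-Makeham mortality hazard `qx(a) = A + B * c^a`, a hump-shaped
#' age-earnings profile (log-quadratic around a mid-career peak), an economic
#' activity rate that ramps up through the early twenties, plateaus, and
#' falls away in the decade before retirement, a background disability
#' prevalence rising exponentially with age, and per-capita health
#' expenditure growing geometrically with age. All outputs are deterministic
#' given the parameters; the seed is recorded for provenance of any future
#' stochastic extension.
#'
#' @param makeham_a Age-independent (Makeham) component of qx.
#' @param gompertz_b Level of the Gompertz term.
#' @param gompertz_c Age slope of the Gompertz term (> 1).
#' @param earnings_peak_age Age of peak gross earnings.
#' @param earnings_peak Peak gross annual earnings (EUR).
#' @param earnings_curvature Log-quadratic curvature of the earnings hump.
#' @param activity_plateau Prime-age economic activity rate.
#' @param disability_slope Exponential age slope of background disability
#'   prevalence (anchored at 2% at age 18).
#' @param gp_cost_base Per-capita health expenditure at age 18 (EUR).
#' @param gp_cost_growth_per_age Geometric growth of health expenditure per
#'   year of age.
#' @param seed Integer recorded with the fixture.
#' @return A `country_generator_params` list.
#' @export
country_generator_params <- function(makeham_a = 2e-4,
                                     gompertz_b = 1e-5,
                                     gompertz_c = 1.11,
                                     earnings_peak_age = 50,
                                     earnings_peak = 55000,
                                     earnings_curvature = 8e-4,
                                     activity_plateau = 0.85,
                                     disability_slope = 0.05,
                                     gp_cost_base = 600,
                                     gp_cost_growth_per_age = 0.025,
                                     seed = 20210804L) {
  p <- list(makeham_a = makeham_a, gompertz_b = gompertz_b,
            gompertz_c = gompertz_c, earnings_peak_age = earnings_peak_age,
            earnings_peak = earnings_peak,
            earnings_curvature = earnings_curvature,
            activity_plateau = activity_plateau,
            disability_slope = disability_slope, gp_cost_base = gp_cost_base,
            gp_cost_growth_per_age = gp_cost_growth_per_age,
            seed = as.integer(seed))
  if (any(c(p$makeham_a, p$gompertz_b) < 0) || p$gompertz_c <= 1) {
    abort("mortality parameters must be positive with gompertz_c > 1",
          class = "ahpfisc_validation_error")
  }
  if (p$activity_plateau <= 0 || p$activity_plateau > 1) {
    abort("activity_plateau must lie in (0, 1]",
          class = "ahpfisc_validation_error")
  }
  structure(p, class = "country_generator_params")
}

#' Generate a Gompertz-Makeham life table
#'
#' `qx(a) = min(1, A + B * c^a)` over ages 0..100, closed at 100.
#'
#' @param p A [country_generator_params()].
#' @param qx_multiplier Optional multiplicative tilt on qx (used by
#'   calibration), bounded so qx stays in `[0, 1]`.
#' @return A [life_table()].
#' @export
make_life_table <- function(p, qx_multiplier = 1) {
  ages <- 0:100
  qx <- pmin(1, qx_multiplier * (p$makeham_a + p$gompertz_b * p$gompertz_c^ages))
  if (any(qx[ages < 60] >= 1)) {
    warn("mortality parameters drive qx to 1 before age 60")
  }
  qx[length(qx)] <- 1
  life_table(tibble(age = ages, qx = qx))
}

#' Generate synthetic age profiles
#'
#' Earnings follow `peak * exp(-curvature * (a - peak_age)^2)`; activity
#' ramps linearly from age 16 to full plateau at 24, holds to 55, then
#' declines linearly to zero at retirement; disability prevalence is
#' `min(0.6, 0.02 * exp(slope * (a - 18)))`; health expenditure is
#' `base * (1 + growth)^(a - 18)`. Optional multiplicative scales (bounded so
#' rates stay in `[0, 1]`) are applied by the calibration.
#'
#' @param p A [country_generator_params()].
#' @param scales Named list of multiplicative factors `earnings`, `activity`,
#'   `disability`, `health` (defaults 1).
#' @return An [age_profiles()] tibble over ages 18..100.
#' @export
make_profiles <- function(p, scales = list()) {
  s <- modifyList(list(earnings = 1, activity = 1, disability = 1, health = 1),
                  scales)
  ages <- 18:100
  earnings <- p$earnings_peak *
    exp(-p$earnings_curvature * (ages - p$earnings_peak_age)^2)
  ramp <- pmin(1, pmax(0, (ages - 15) / 9))
  taper <- pmin(1, pmax(0, (65 - ages) / 10))
  activity <- p$activity_plateau * pmin(ramp, taper)
  disability <- pmin(0.6, 0.02 * exp(p$disability_slope * (ages - 18)))
  gp_cost <- p$gp_cost_base * (1 + p$gp_cost_growth_per_age)^(ages - 18)
  age_profiles(tibble(
    age = ages,
    gross_earnings = s$earnings * earnings,
    activity_rate = pmin(1, s$activity * activity),
    disability_rate = pmin(1, s$disability * disability),
    gp_health_cost = s$health * gp_cost
  ))
}

#' Lifetime totals of the reference general-population column
#'
#' The published lifetime totals (EUR, discounted at 3%) for the Belgian
#' general-population comparator that [calibrate_fixture()] targets.
#'
#' @return Named numeric vector of the seven summary fields.
#' @export
gp_calibration_targets <- function() {
  c(disability_transfers = 40277, pension_costs = 83110, health_costs = 70218,
    sum_government_costs = 193605, lifetime_earnings = 632367,
    gross_tax = 434722, work_years = 25.24)
}

gp_summary_for <- function(lt, profiles, params) {
  fiscal_summary(project_scenario(scenario_gp(), lt, profiles, params))
}

#' Calibrate the synthetic country to reference lifetime totals
#'
#' Tilts mortality (a single multiplier on qx, solved so the lifetime pension
#' cost matches its target) and then applies multiplicative scale factors to
#' the activity, earnings, disability and health schedules so the
#' general-population projection reproduces the target lifetime totals. The
#' activity scale is solved by root finding (rates are clipped at 1); the
#' remaining scales follow linearly. Gross tax is structurally tied to
#' lifetime earnings through the combined tax rate and gets no independent
#' degree of freedom, so its residual is reported rather than fitted.
#'
#' @param targets Named vector as [gp_calibration_targets()].
#' @param p A [country_generator_params()].
#' @param params A [fiscal_parameters()] object.
#' @param tol Relative tolerance on each fitted target.
#' @param max_iter Maximum outer refinement sweeps.
#' @return An `ahp_fixture` list: `life_table`, `profiles`, `scales`
#'   (including `qx_multiplier`), `summary` (achieved GP summary),
#'   `residuals` (relative, per target), `diagnostics` (including the
#'   pre-onset earnings of the never-working scenario), `generator`, and
#'   `params`.
#' @export
calibrate_fixture <- function(targets = gp_calibration_targets(),
                              p = country_generator_params(),
                              params = fiscal_parameters(),
                              tol = 0.02, max_iter = 5) {
  # 1. mortality tilt: pension cost depends only on survival and constants
  pension_gap <- function(k) {
    lt <- make_life_table(p, qx_multiplier = k)
    surv <- conditional_survival(lt, params$base_age, params$horizon_age)
    ps <- pension_stream(params)
    s <- surv$survival[match(ps$age, surv$age)] %na% 1
    d <- discount_factors(ps$age, params$discount_rate, params$base_age)
    sum(ps$amount * s * d) - targets[["pension_costs"]]
  }
  k <- uniroot(pension_gap, c(0.05, 25), tol = 1e-10)$root
  lt <- make_life_table(p, qx_multiplier = k)

  scales <- list(earnings = 1, activity = 1, disability = 1, health = 1)
  for (i in seq_len(max_iter)) {
    # 2. activity scale: work years (clipping at rate 1 makes this nonlinear)
    wy_gap <- function(s_act) {
      pr <- make_profiles(p, modifyList(scales, list(activity = s_act)))
      gp_summary_for(lt, pr, params)$work_years - targets[["work_years"]]
    }
    scales$activity <- uniroot(wy_gap, c(0.01, 10), tol = 1e-9)$root
    # 3-5. linear scales
    cur <- gp_summary_for(lt, make_profiles(p, scales), params)
    scales$earnings <- scales$earnings *
      targets[["lifetime_earnings"]] / cur$lifetime_earnings
    scales$disability <- scales$disability *
      targets[["disability_transfers"]] / cur$disability_transfers
    scales$health <- scales$health *
      targets[["health_costs"]] / cur$health_costs
    profiles <- make_profiles(p, scales)
    achieved <- gp_summary_for(lt, profiles, params)
    fitted <- c("lifetime_earnings", "disability_transfers", "health_costs",
                "work_years", "pension_costs")
    resid <- vapply(names(targets), function(f) {
      achieved[[f]] / targets[[f]] - 1
    }, numeric(1))
    if (all(abs(resid[fitted]) < tol)) break
  }
  if (!all(abs(resid[fitted]) < tol)) {
    warn(paste0("calibration did not reach tolerance on: ",
                paste(fitted[abs(resid[fitted]) >= tol], collapse = ", ")))
  }

  al_w <- fiscal_summary(project_scenario(scenario_al_w(), lt, profiles, params))
  structure(list(
    life_table = lt, profiles = profiles,
    scales = c(scales, qx_multiplier = k),
    summary = achieved, residuals = resid,
    diagnostics = list(pre_onset_earnings = al_w$lifetime_earnings,
                       pre_onset_work_years = al_w$work_years),
    generator = p, params = params
  ), class = "ahp_fixture")
}

fixture_cache <- new.env(parent = emptyenv())

#' The calibrated Belgian-like fixture
#'
#' Convenience wrapper: generates and calibrates the synthetic country with
#' default generator parameters and caches the result for the session.
#'
#' @param refresh Recompute even if cached.
#' @return An `ahp_fixture` (see [calibrate_fixture()]).
#' @export
belgian_fixture <- function(refresh = FALSE) {
  if (refresh || is.null(fixture_cache$fx)) {
    fixture_cache$fx <- calibrate_fixture()
  }
  fixture_cache$fx
}

#' Write a fixture to CSV files
#'
#' Writes `life_table.csv` (`age,qx`) and `profiles.csv`
#' (`age,gross_earnings,activity_rate,disability_rate,gp_health_cost`) in the
#' formats read back by [read_life_table()] and [read_age_profiles()].
#' Deterministic: identical fixtures give byte-identical files.
#'
#' @param fixture An `ahp_fixture` (or any list with `life_table` and
#'   `profiles`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lt_path <- file.path(dir, "life_table.csv")
  pr_path <- file.path(dir, "profiles.csv")
  readr::write_csv(fixture$life_table, lt_path)
  readr::write_csv(fixture$profiles, pr_path)
  invisible(c(life_table = lt_path, profiles = pr_path))
}
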