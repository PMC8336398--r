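#' Construct and validate a life table
#'
#' A life table is the package's container for age-specific mortality: one row
#' per single year of age with the annual probability of death `qx`. All
#' survival weighting in the projection engine derives from it.
#'
#' @param x A data frame with integer column `age` (contiguous, ascending) and
#'   numeric column `qx` in `[0, 1]`. The terminal age must have `qx = 1`
#'   (closed table).
#' @return A `life_table` tibble with columns `age` and `qx`.
#' @examples
#' lt <- life_table(data.frame(age = 0:100, qx = c(rep(0.01, 100), 1)))
#' @export
life_table <- function(x) {
  x <- as_tibble(x)
  for (col in c("age", "qx")) {
    if (!col %in% names(x)) {
      abort(sprintf("life table is missing required column '%s'", col),
            class = "ahpfisc_format_error")
    }
  }
  x <- x[c("age", "qx")]
  if (nrow(x) < 2) {
    abort("life table needs at least two ages", class = "ahpfisc_format_error")
  }
  if (any(x$age != as.integer(x$age))) {
    abort("life table ages must be integers", class = "ahpfisc_format_error")
  }
  x$age <- as.integer(x$age)
  bad <- which(is.na(x$qx) | x$qx < 0 | x$qx > 1)
  if (length(bad) > 0) {
    abort(sprintf("qx outside [0, 1] at age %d (row %d)", x$age[bad[1]], bad[1]),
          class = "ahpfisc_format_error")
  }
  gaps <- which(diff(x$age) != 1L)
  if (length(gaps) > 0) {
    abort(sprintf("life table ages must be contiguous: gap after age %d (row %d)",
                  x$age[gaps[1]], gaps[1]),
          class = "ahpfisc_format_error")
  }
  if (x$qx[nrow(x)] != 1) {
    abort(sprintf("life table must be closed: qx at terminal age %d is %g, not 1",
                  x$age[nrow(x)], x$qx[nrow(x)]),
          class = "ahpfisc_format_error")
  }
  class(x) <- c("life_table", class(x))
  x
}

#' Read a life table from CSV
#'
#' Expects a UTF-8 comma-separated file with header `age,qx` and a period
#' decimal separator, e.g. as written by [write_fixture()].
#'
#' @param path Path to the CSV file.
#' @return A validated [life_table()].
#' @export
read_life_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  life_table(x)
}

#' Read age-indexed economic profiles from CSV
#'
#' Expects header `age,gross_earnings,activity_rate,disability_rate,gp_health_cost`:
#' per single year of age, average gross annual earnings (EUR), the economic
#' activity rate and background disability prevalence (both fractions in
#' `[0, 1]`), and per-capita annual health expenditure of the general
#' population (EUR).
#'
#' @param path Path to the CSV file.
#' @return A validated profile tibble (see [age_profiles()]).
#' @export
read_age_profiles <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  age_profiles(x)
}

#' Validate an age-profile table
#'
#' @param x Data frame with columns `age`, `gross_earnings`, `activity_rate`,
#'   `disability_rate`, `gp_health_cost`.
#' @return The validated tibble.
#' @export
age_profiles <- function(x) {
  x <- as_tibble(x)
  needed <- c("age", "gross_earnings", "activity_rate", "disability_rate",
              "gp_health_cost")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("profile table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ahpfisc_format_error")
  }
  x <- x[needed]
  x$age <- as.integer(x$age)
  if (any(diff(x$age) != 1L)) {
    abort("profile ages must be contiguous", class = "ahpfisc_format_error")
  }
  for (col in c("activity_rate", "disability_rate")) {
    bad <- which(x[[col]] < 0 | x[[col]] > 1)
    if (length(bad) > 0) {
      abort(sprintf("%s outside [0, 1] at age %d", col, x$age[bad[1]]),
            class = "ahpfisc_format_error")
    }
  }
  if (any(x$gross_earnings < 0) || any(x$gp_health_cost < 0)) {
    abort("earnings and health costs must be non-negative",
          class = "ahpfisc_format_error")
  }
  x
}

#' Conditional survival curve from a life table
#'
#' Probability of being alive at the start of each age, conditional on being
#' alive at `base_age`: `S(base_age) = 1` and
#' `S(a + 1) = S(a) * (1 - qx(a))`.
#'
#' @param lt A [life_table()].
#' @param base_age Conditioning age (model start).
#' @param horizon_age Last age of the curve.
#' @return A tibble with columns `age` and `survival`, ages
#'   `base_age:horizon_age`.
#' @export
conditional_survival <- function(lt, base_age, horizon_age) {
  if (base_age >= horizon_age) {
    abort("base_age must be below horizon_age", class = "ahpfisc_range_error")
  }
  rng <- range(lt$age)
  if (base_age < rng[1] || horizon_age > rng[2]) {
    abort(sprintf("ages %d..%d outside life-table range %d..%d",
                  base_age, horizon_age, rng[1], rng[2]),
          class = "ahpfisc_range_error")
  }
  ages <- base_age:horizon_age
  qx <- lt$qx[match(ages, lt$age)]
  s <- cumprod(c(1, 1 - qx[-length(qx)]))
  tibble(age = ages, survival = s)
}

#' Start-of-year discount factors
#'
#' Cashflows are booked at the start of each model year; the factor for age
#' `a` is `(1 + rate)^-(a - base_age)`. Ages before `base_age` (the pre-model
#' earnings window) are not compounded upward: their factor is clamped to 1.
#'
#' @param ages Integer ages.
#' @param rate Annual discount rate (fraction).
#' @param base_age Model start age (discounting origin).
#' @return Numeric vector of discount factors.
#' @export
discount_factors <- function(ages, rate, base_age) {
  (1 + rate)^(-pmax(0, ages - base_age))
}

#' Discounted expected years in work
#'
#' Sums the activity rate over ages `entry_age` to `retirement_age - 1`,
#' weighted by conditional survival and the start-of-year discount factor.
#' Ages missing from the survival curve but below its base age count as
#' survival 1 (the curve conditions on being alive at the model start).
#'
#' @param activity Tibble with columns `age` and `value` (activity rate in
#'   `[0, 1]`), or `age` and `activity_rate`.
#' @param survival Tibble as returned by [conditional_survival()].
#' @param discount_rate Annual discount rate.
#' @param entry_age,retirement_age Work window; the last worked age is
#'   `retirement_age - 1`.
#' @param base_age Discounting origin.
#' @return Expected work years (scalar).
#' @export
expected_work_years <- function(activity, survival, discount_rate,
                                entry_age, retirement_age, base_age) {
  if (entry_age >= retirement_age) {
    abort("entry_age must be below retirement_age", class = "ahpfisc_range_error")
  }
  val_col <- if ("value" %in% names(activity)) "value" else "activity_rate"
  act <- tibble(age = activity$age, value = activity[[val_col]])
  if (any(act$value < 0 | act$value > 1)) {
    abort("activity values must lie in [0, 1]", class = "ahpfisc_range_error")
  }
  ages <- intersect(entry_age:(retirement_age - 1), act$age)
  if (length(ages) == 0) {
    abort("activity schedule does not overlap the work window",
          class = "ahpfisc_range_error")
  }
  a <- act$value[match(ages, act$age)]
  s <- survival$survival[match(ages, survival$age)]
  below_base <- ages < min(survival$age)
  s[below_base] <- 1
  if (any(is.na(s))) {
    abort("survival curve does not cover the work window",
          class = "ahpfisc_range_error")
  }
  d <- discount_factors(ages, discount_rate, base_age)
  sum(a * s * d)
}
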