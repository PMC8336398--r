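config_keys <- c("fiscal", "attack_cost", "management_costs", "scenarios",
                 "paths", "generator", "output")

builtin_scenarios <- c("gp", "al_w", "a10_w", "a10_plus_w")

#' Default run configuration
#'
#' The shipped defaults encode the Belgian reference case end to end: the
#' default [fiscal_parameters()], the default [attack_cost_lines()] and
#' [management_costs()], all four built-in scenarios, no input paths (the
#' calibrated synthetic fixture is generated), and whole-euro rounding of
#' report cells.
#'
#' @return An `ahp_config` object.
#' @export
default_config <- function() {
  parse_config(list())
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file, fills unspecified fields with
#' the shipped defaults, and re-validates every cross-field invariant through
#' the same constructors used by the engine. An empty file yields
#' [default_config()].
#'
#' @param path Path to the configuration file.
#' @return An `ahp_config` object.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  parse_config(raw)
}

parse_config <- function(raw) {
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "ahpfisc_validation_error")
  }
  params <- do.call(fiscal_parameters, raw$fiscal %||% list())
  attack_table <- if (is.null(raw$attack_cost)) {
    attack_cost_lines()
  } else {
    lines <- purrr::map_dfr(raw$attack_cost, function(l) {
      tibble(resource = l$resource,
             pct_receiving = l$pct %||% l$pct_receiving %||% 1,
             units = l$units %||% NA_real_,
             unit_cost = l$unit_cost %||% NA_real_,
             canonical_total = l$canonical_total %||% NA_real_)
    })
    attack_cost_lines(lines)
  }
  mgmt <- do.call(management_costs, raw$management_costs %||% list())
  scen_names <- raw$scenarios %||% builtin_scenarios
  bad <- setdiff(scen_names, builtin_scenarios)
  if (length(bad) > 0) {
    abort(paste0("unknown scenario name(s): ", paste(bad, collapse = ", ")),
          class = "ahpfisc_validation_error")
  }
  if (anyDuplicated(scen_names)) {
    abort("scenario names must be unique", class = "ahpfisc_validation_error")
  }
  scenarios <- ahp_scenarios()[scen_names]
  if (!is.null(raw$paths)) {
    for (f in unlist(raw$paths)) {
      if (!file.exists(f)) {
        abort(sprintf("configured input file does not exist: %s", f),
              class = "ahpfisc_validation_error")
      }
    }
  }
  generator <- do.call(country_generator_params, raw$generator %||% list())
  output <- modifyList(list(dir = ".", rounding = "euro"),
                       raw$output %||% list())
  structure(list(raw = raw, params = params, attack_table = attack_table,
                 mgmt = mgmt, scenarios = scenarios, paths = raw$paths,
                 generator = generator, output = output),
            class = "ahp_config")
}

#' Write a configuration back to YAML
#'
#' Only explicitly set fields are written, so `load -> dump -> load` is
#' stable.
#'
#' @param config An `ahp_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Run the full pipeline for a configuration
#'
#' Resolves the model inputs (reading the configured life-table and profile
#' CSVs, or generating and calibrating the synthetic fixture), projects every
#' configured scenario, summarises lifetime totals, computes deltas against
#' the general-population comparator, assembles the seven-row results table
#' with change columns, per-age chart data, and the tornado of the one-way
#' sensitivity analysis. Deterministic given the configuration.
#'
#' @param config An `ahp_config` (default [default_config()]).
#' @return An `ahp_results` list: `ledgers`, `summaries`, `deltas`, `table`
#'   (rounded report table), `chart_data`, `tornado`, `fixture`, `log`.
#' @export
run_all <- function(config = default_config()) {
  if (!is.null(config$paths)) {
    fixture <- list(life_table = read_life_table(config$paths$life_table),
                    profiles = read_age_profiles(config$paths$profiles))
  } else {
    # the synthetic country is calibrated once, under the reference fiscal
    # parameters; the configured parameters are an analysis choice and must
    # not be absorbed by recalibration
    fixture <- calibrate_fixture(p = config$generator)
  }
  project1 <- function(spec) {
    project_scenario(spec, fixture$life_table, fixture$profiles,
                     config$params, attack_table = config$attack_table,
                     mgmt = config$mgmt)
  }
  ledgers <- purrr::map(config$scenarios, project1)
  summaries <- purrr::map(ledgers, fiscal_summary)
  has_gp <- "gp" %in% names(summaries)
  deltas <- if (has_gp) {
    purrr::map(summaries[setdiff(names(summaries), "gp")],
               fiscal_delta, gp = summaries$gp)
  } else {
    list()
  }
  chart_data <- if (has_gp) {
    purrr::map(ledgers[setdiff(names(ledgers), "gp")],
               annual_chart_data, gp_ledger = ledgers$gp)
  } else {
    list()
  }
  tornado <- if ("a10_w" %in% names(config$scenarios)) {
    owsa(fixture, spec = config$scenarios$a10_w, params = config$params,
         mgmt = config$mgmt,
         attack_cost = attack_cost_total(config$attack_table))
  } else {
    NULL
  }
  log <- list(
    package_version = as.character(packageVersion("ahpfisc")),
    config_hash = rlang::hash(config$raw),
    seed = config$generator$seed,
    parameters = unclass(config$params),
    scales = if (inherits(fixture, "ahp_fixture")) fixture$scales else NULL
  )
  structure(list(ledgers = ledgers, summaries = summaries, deltas = deltas,
                 table = results_table(summaries, deltas, config$output$rounding),
                 chart_data = chart_data, tornado = tornado,
                 fixture = fixture, log = log, config = config),
            class = "ahp_results")
}

result_row_labels <- c(
  disability_transfers = "Disability transfers",
  pension_costs = "Pension costs",
  health_costs = "Health costs",
  sum_government_costs = "Sum of government costs",
  lifetime_earnings = "Lifetime earnings",
  gross_tax = "Gross tax",
  work_years = "Work years"
)

round_cell <- function(value, field, rounding) {
  if (field == "work_years") return(round_half_up(value, 2))
  switch(rounding,
         euro = round_half_up(value, 0),
         cent = round_half_up(value, 2),
         none = value,
         abort(sprintf("unknown rounding rule '%s'", rounding),
               class = "ahpfisc_validation_error"))
}

# Seven-row report table: one column per scenario plus a change column per
# non-comparator scenario. Cells are summary fields rounded per the rule --
# no arithmetic happens at the report layer.
results_table <- function(summaries, deltas, rounding = "euro") {
  fields <- names(result_row_labels)
  out <- tibble(metric = unname(result_row_labels))
  for (nm in names(summaries)) {
    s <- summaries[[nm]]
    out[[s$scenario]] <- unname(vapply(fields, function(f) {
      round_cell(s[[f]], f, rounding)
    }, numeric(1)))
    if (nm %in% names(deltas)) {
      d <- deltas[[nm]]
      out[[paste0("Change (", d$scenario, ")")]] <- unname(vapply(fields, function(f) {
        round_cell(d[[f]], f, rounding)
      }, numeric(1)))
    }
  }
  out
}

markdown_table <- function(df) {
  fmt <- function(x) {
    if (!is.numeric(x)) return(x)
    vapply(x, function(v) {
      digits <- if (v == round(v)) 0 else 2
      formatC(v, format = "f", digits = digits, big.mark = ",")
    }, character(1))
  }
  cells <- purrr::map_dfc(df, fmt)
  header <- paste0("| ", paste(names(cells), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(cells)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Write result files
#'
#' Writes the results table (CSV and markdown), per-scenario chart data, the
#' tornado CSV, and a YAML run log recording the package version, the
#' configuration hash and every resolved parameter.
#'
#' @param results An `ahp_results` from [run_all()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_results <- function(results, dir = results$config$output$dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "results.csv")
  readr::write_csv(results$table, p)
  paths <- c(paths, p)
  p <- file.path(dir, "results.md")
  writeLines(markdown_table(results$table), p)
  paths <- c(paths, p)
  for (nm in names(results$chart_data)) {
    p <- file.path(dir, paste0("chart_data_", nm, ".csv"))
    readr::write_csv(as_tibble(results$chart_data[[nm]]), p)
    paths <- c(paths, p)
  }
  if (!is.null(results$tornado)) {
    p <- file.path(dir, "tornado.csv")
    readr::write_csv(as_tibble(results$tornado), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "run_log.yaml")
  yaml::write_yaml(results$log, p)
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.ahp_results <- function(x, ...) {
  cat("<ahp_results>\n")
  print(x$table)
  invisible(x)
}
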