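#' Plot annual fiscal differences versus the comparator
#'
#' Stacked annual chart: tax differences plotted upward, incremental
#' government cost categories downward, per age, all survival-weighted and
#' discounted.
#'
#' @param object An [annual_chart_data()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.annual_chart_data <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("disability", "pension", "health_cost"),
                              names_to = "category", values_to = "value")
  long$value <- -long$value  # costs shown below the axis
  taxes <- as_tibble(object)[c("age", "tax_difference")]
  ggplot2::ggplot() +
    ggplot2::geom_col(data = long,
                      ggplot2::aes(x = .data$age, y = .data$value,
                                   fill = .data$category)) +
    ggplot2::geom_col(data = taxes,
                      ggplot2::aes(x = .data$age, y = .data$tax_difference),
                      fill = "grey30") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Age", y = "EUR per year (discounted)",
                  fill = "Government cost",
                  title = paste0("Annual fiscal impact: ",
                                 attr(object, "scenario") %||% "scenario",
                                 " vs GP")) +
    ggplot2::theme_minimal()
}

#' Tornado diagram for a one-way sensitivity analysis
#'
#' Horizontal bars from the low to the high output for each varied
#' parameter, widest range on top.
#'
#' @param object A `tornado` tibble from [owsa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tornado <- function(object, ...) {
  x <- arrange(as_tibble(object), .data$range)
  x$parameter <- factor(x$parameter, levels = x$parameter)
  ggplot2::ggplot(x, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$low_output,
                                       xend = .data$high_output,
                                       yend = .data$parameter),
                          linewidth = 6, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = x$base_output[1], linetype = 2) +
    ggplot2::labs(x = paste0(attr(object, "output") %||% "output", " (EUR)"),
                  y = NULL,
                  title = sprintf("One-way sensitivity (+/-%d%% variation)",
                                  round(100 * (attr(object, "fraction") %||% 0.25)))) +
    ggplot2::theme_minimal()
}

#' Plot the annual streams of a cashflow ledger
#'
#' @param object A `cashflow_ledger`.
#' @param weighted Plot survival-weighted, discounted amounts (default) or
#'   nominal amounts.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cashflow_ledger <- function(object, weighted = TRUE, ...) {
  cols <- c("earnings", "direct_tax", "indirect_tax", "disability", "pension",
            "health_cost")
  x <- as_tibble(object)
  if (weighted) {
    for (col in cols) x[[col]] <- x[[col]] * x$survival * x$discount
  }
  long <- tidyr::pivot_longer(x[c("age", cols)], dplyr::all_of(cols),
                              names_to = "stream", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$value,
                                     colour = .data$stream)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age",
                  y = if (weighted) "EUR per year (discounted, survival-weighted)"
                      else "EUR per year (nominal)",
                  colour = NULL,
                  title = paste0("Annual streams: ",
                                 attr(object, "spec")$name %||% "scenario")) +
    ggplot2::theme_minimal()
}
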