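#' Bar chart of event cases per year
#'
#' @param yearly Tibble from [yearly_counts()].
#' @return A ggplot object.
#' @export
plot_yearly_counts <- function(yearly) {
  ggplot2::ggplot(yearly, ggplot2::aes(x = .data$year, y = .data$n_cases)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "FDA receipt year", y = "Event cases") +
    ggplot2::theme_minimal()
}

#' Histogram of binned onset times
#'
#' @param bins Tibble from [onset_bins()].
#' @return A ggplot object.
#' @export
plot_onset_bins <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$n_cases)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Days from therapy start to event", y = "Cases") +
    ggplot2::theme_minimal()
}

#' Forest plot of the strongest signals
#'
#' Plots the ROR point estimates and 95% confidence intervals for the top
#' evaluable drugs, log-scaled, with the signal threshold at 1.
#'
#' @param object A `faers_signals` object from [analyze_signals()].
#' @param top_n Number of drugs shown, ranked by ROR (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faers_signals
#' @export
autoplot.faers_signals <- function(object, top_n = 25, ...) {
  top <- rank_signals(object, "ror", top_n) |>
    dplyr::mutate(
      ingredient_key = factor(.data$ingredient_key,
                              levels = rev(.data$ingredient_key))
    )
  ggplot2::ggplot(top, ggplot2::aes(x = .data$ror, y = .data$ingredient_key)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$ror_signal)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Reporting odds ratio (95% CI, log scale)", y = NULL,
      colour = "ROR signal"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
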