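#' Plot the yearly score trend
#'
#' Mean composite score per year with a +/- 1 SD ribbon.
#'
#' @param object An `rti_trend` tibble from [trend_table()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot rti_trend
#' @export
autoplot.rti_trend <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$mean_score)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$mean_score - .data$sd_score),
                   ymax = pmin(10, .data$mean_score + .data$sd_score)),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 10)) +
    ggplot2::labs(x = "Year", y = "Mean composite score (0-10)",
                  title = "Rigor and transparency score over time") +
    ggplot2::theme_minimal()
}

#' Plot criterion-adherence trends by year
#'
#' @param trend An `rti_trend` tibble from [trend_table()].
#' @param criteria Which criteria to show (default: randomization, blinding,
#'   power, sex).
#' @return A ggplot object.
#' @export
plot_criterion_trends <- function(trend,
                                  criteria = c("RANDOMIZATION", "BLINDING",
                                               "POWER", "SEX")) {
  cols <- paste0("rate_", criteria)
  long <- trend |>
    dplyr::select("year", dplyr::all_of(cols)) |>
    tidyr::pivot_longer(-"year", names_to = "criterion",
                        values_to = "rate") |>
    dplyr::mutate(criterion = sub("^rate_", "", .data$criterion))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = 100 * .data$rate,
                                     colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Year", y = "Papers addressing criterion (%)",
                  colour = "Criterion") +
    ggplot2::theme_minimal()
}

#' Scatter plot of journal RTI against impact factor
#'
#' @param comparison An `rti_jif_comparison` from [compare_with_jif()].
#' @param percentile If `TRUE`, plot percentile ranks (quartile axes) instead
#'   of raw values.
#' @return A ggplot object.
#' @export
plot_rti_vs_jif <- function(comparison, percentile = FALSE) {
  d <- comparison$data
  if (percentile) {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$jif_percentile,
                                         y = .data$rti_percentile)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = "Impact-factor percentile",
                    y = "RTI percentile") +
      ggplot2::scale_x_continuous(breaks = c(12.5, 37.5, 62.5, 87.5),
                                  labels = c("Q4", "Q3", "Q2", "Q1")) +
      ggplot2::scale_y_continuous(breaks = c(12.5, 37.5, 62.5, 87.5),
                                  labels = c("Q4", "Q3", "Q2", "Q1"))
    rs <- comparison$spearman_percentile$coefficient
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$jif, y = .data$rti)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = "Journal Impact Factor", y = "Rigor and Transparency Index")
    rs <- comparison$spearman_raw$coefficient
  }
  p +
    ggplot2::ggtitle(sprintf("RTI vs JIF (Spearman Rs = %.4f, n = %d)",
                             rs, nrow(d))) +
    ggplot2::theme_minimal()
}
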