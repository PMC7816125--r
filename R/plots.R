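#' Plot a simulated trajectory
#'
#' All model variables over time, faceted into concentrations (Im, Ip)
#' and rates (I1, I2, It), with located switching events as dashed
#' vertical lines.
#'
#' @param object An `ime_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ime_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time", "Im", "Ip", "I1", "I2", "It")],
    -"time", names_to = "variable", values_to = "value")
  long$panel <- ifelse(long$variable %in% c("Im", "Ip"),
                       "concentrations", "rates")
  ev <- circuit_events(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                          colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::labs(x = "time (h)", y = "level (scaled)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(ev)) {
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$time),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a steady-state dose-response curve
#'
#' Ime1 protein steady state against Rme1 concentration (log10 x axis;
#' r = 0 is drawn at the left edge).
#'
#' @param object An `ime_dose_response`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ime_dose_response <- function(object, ...) {
  df <- tibble::as_tibble(object)
  r_floor <- min(df$r[df$r > 0], 1e-3) / 2
  df$r_plot <- pmax(df$r, r_floor)
  ggplot2::ggplot(df, ggplot2::aes(.data$r_plot, .data$Ip_star)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Rme1 concentration r (log scale)",
                  y = "Ime1 protein steady state Ip*",
                  title = attr(object, "mode")) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic single-cell copy-number population
#'
#' Histogram of per-cell mRNA copy counts with the high-expresser
#' threshold marked.
#'
#' @param object An `ime_cell_population`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ime_cell_population <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$copies)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0) +
    ggplot2::geom_vline(xintercept = attr(object, "threshold") + 0.5,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "mRNA copies per cell", y = "cells",
                  subtitle = sprintf("fraction high = %.3f",
                                     attr(object, "fraction_high"))) +
    ggplot2::theme_minimal()
}

#' Plot a parameter-recovery experiment
#'
#' Per-parameter relative-error distributions across replicates.
#'
#' @param object An `ime_recovery`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ime_recovery <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$term, .data$rel_error)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "relative error |est - truth| / truth") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
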