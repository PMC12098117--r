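#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a lag-response curve
#'
#' Line of per-lag RR with a shaded 95% CI ribbon and a reference line at
#' RR = 1, the conventional presentation of a distributed-lag risk curve.
#'
#' @param object A `lag_curve` from [lag_rr()] (or the pipeline's
#'   `lag_curves` tibble, faceted by cause).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lag_curve
#' @export
autoplot.lag_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$rr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25, fill = "#2166AC") +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::labs(x = "Lag (days since flooded day)",
                  y = "Relative risk") +
    ggplot2::theme_minimal()
  if ("cause" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~cause, scales = "free_y")
  }
  p
}

#' Forest-style plot of cumulative RRs
#'
#' @param data Tibble with columns `estimate`, `ci_low`, `ci_high` and a
#'   labelling column (default `cause`).
#' @param label Column used for the y axis.
#' @return A ggplot object.
#' @export
plot_cum_rr <- function(data, label = "cause") {
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data$estimate,
                               y = .data[[label]])) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2, colour = "#2166AC") +
    ggplot2::geom_point(size = 2, colour = "#2166AC") +
    ggplot2::labs(x = "Cumulative relative risk over the lag window",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot attributable fractions with empirical CIs
#'
#' @param data Tibble with `af`, `eci_low`, `eci_high` and a labelling
#'   column (default `cause`).
#' @param label Column used for the y axis.
#' @return A ggplot object.
#' @export
plot_af <- function(data, label = "cause") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$af, y = .data[[label]])) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$eci_low,
                                         xmax = .data$eci_high),
                            height = 0.2, colour = "#B2182B") +
    ggplot2::geom_point(size = 2, colour = "#B2182B") +
    ggplot2::labs(x = "Attributable fraction (%)", y = NULL) +
    ggplot2::theme_minimal()
}
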