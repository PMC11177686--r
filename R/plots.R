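# Static figure exports (ggplot2, Suggests-only): CEAC, tornado,
# cost-effectiveness plane.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the `ggplot2` package", call. = FALSE)
  }
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `ceac_curve` from [ceac()].
#' @param wtp Optional WTP threshold to mark with a vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve, wtp = NULL) {
  need_ggplot()
  p <- ggplot2::ggplot(as.data.frame(curve),
                       ggplot2::aes(x = .data$wtp,
                                    y = .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = "dashed")
  }
  p
}

#' Plot a tornado diagram of the one-way sensitivity analysis
#'
#' Bars span each parameter's ICER (signed `delta_cost / delta_qalys`)
#' at its low and high bound, around the base-case value.
#'
#' @param dsa A `dsa_result` from [one_way_dsa()].
#' @param top Number of parameters to show (widest spans first).
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa, top = 12) {
  need_ggplot()
  df <- utils::head(as.data.frame(dsa), top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_low,
                                       xend = .data$icer_at_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(dsa, "base_icer"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Plot the PSA cost-effectiveness plane
#'
#' Scatter of incremental QALYs vs incremental cost per draw, with the
#' WTP threshold line through the origin.
#'
#' @param draws A `psa_draws` from [run_psa()].
#' @param wtp WTP threshold (USD/QALY); defaults to the draws' attribute.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, wtp = attr(draws, "wtp")) {
  need_ggplot()
  df <- as.data.frame(draws)
  df <- df[!is.na(df$delta_qalys), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_qalys,
                                        y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed")
  }
  p
}
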