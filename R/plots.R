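#' Cost-effectiveness plane
#'
#' Scatter of incremental cost against incremental QALYs per simulation,
#' with the willingness-to-pay threshold as a reference line.
#'
#' @param cp data frame from [ce_plane()].
#' @param wtp willingness-to-pay threshold drawn as a line.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(cp, wtp = 50000) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ce_plane() needs the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(cp, ggplot2::aes(x = delta_qaly, y = delta_cost,
                                   colour = strategy)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (AU$)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param cc data frame from [ceac()].
#' @return a ggplot object.
#' @export
plot_ceac <- function(cc) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ceac() needs the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(cc, ggplot2::aes(x = wtp, y = fraction,
                                   colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (AU$/QALY)",
                  y = "Probability most cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Horizontal bars spanning the ICER range produced by each one-way
#' parameter variation, widest swing on top.
#'
#' @param tor data frame from [tornado()].
#' @param top number of parameters shown.
#' @return a ggplot object.
#' @export
plot_tornado <- function(tor, top = 10) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tornado() needs the ggplot2 package", call. = FALSE)
  }
  d <- utils::head(tor[order(-tor$swing), ], top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d, ggplot2::aes(y = parameter,
                                  xmin = pmin(icer_at_low, icer_at_high),
                                  xmax = pmax(icer_at_low, icer_at_high))) +
    ggplot2::geom_linerange(linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "ICER (AU$/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}
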