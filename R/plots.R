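#' Cost-utility plane of PSA iterations
#'
#' Scatter of incremental QALYs against incremental costs, one point per
#' PSA iteration, with the willingness-to-pay threshold drawn through the
#' origin.
#'
#' @param psa A `tm_psa` tibble.
#' @param wtp Willingness-to-pay threshold line (CAD/QALY); `NULL` omits it.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 50000) {
  p <- ggplot2::ggplot(psa,
                       ggplot2::aes(x = .data$delta_qaly,
                                    y = .data$delta_cost,
                                    colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = "Incremental QALYs",
                  y = "Incremental cost (CAD)",
                  colour = NULL,
                  title = "Cost-utility plane") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed", colour = "grey30")
  }
  p
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param x A `tm_ceac` tibble from [ceac()].
#' @param wtp_mark Threshold to mark with a vertical reference line
#'   (default 50,000 CAD/QALY); `NULL` omits it.
#' @return A ggplot object.
#' @export
plot_ceac <- function(x, wtp_mark = 50000) {
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (CAD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp_mark)) {
    p <- p + ggplot2::geom_vline(xintercept = wtp_mark, linetype = "dashed",
                                 colour = "grey30")
  }
  p
}

#' @rdname plot_ce_plane
#' @param object A `tm_psa` tibble.
#' @param ... Passed on to [plot_ce_plane()].
#' @export
autoplot.tm_psa <- function(object, ...) plot_ce_plane(object, ...)

#' @rdname plot_ceac
#' @param object A `tm_ceac` tibble.
#' @param ... Passed on to [plot_ceac()].
#' @export
autoplot.tm_ceac <- function(object, ...) plot_ceac(object, ...)
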