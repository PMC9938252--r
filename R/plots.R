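# Minimal rendered charts for the sensitivity outputs (ggplot2 optional).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("install ggplot2 to render charts; the data frames are available ",
         "without it", call. = FALSE)
  }
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param curve A [ceac()] data frame.
#' @param wtp Optional WTP threshold drawn as a vertical reference line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve, wtp = NULL) {
  need_ggplot()
  p <- ggplot2::ggplot(curve, ggplot2::aes(
    x = wtp, y = probability, colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp,
                                                  linetype = "dashed")
  p
}

#' Plot a tornado diagram of incremental net monetary benefit
#'
#' @param tornado A [one_way_dsa()] data frame.
#' @param top Number of parameters to display (widest first).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 10L) {
  need_ggplot()
  d <- tornado[!tornado$flagged & tornado$range > 0, , drop = FALSE]
  d <- utils::head(d, top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base_nmb <- attr(tornado, "base_nmb")
  ggplot2::ggplot(d, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = nmb_at_low,
                                       xend = nmb_at_high,
                                       yend = parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_nmb, linetype = "dashed") +
    ggplot2::labs(x = "Incremental net monetary benefit (USD)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the incremental cost-effectiveness plane
#'
#' @param plane A [ce_plane()] data frame.
#' @param wtp Optional WTP threshold drawn as a ray through the origin.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(plane, wtp = NULL) {
  need_ggplot()
  p <- ggplot2::ggplot(plane, ggplot2::aes(
    x = delta_qalys, y = delta_cost, colour = strategy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                                   linetype = "dashed")
  p
}
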