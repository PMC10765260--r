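#' Plot the cost-effectiveness plane
#'
#' Scatter of incremental cost against incremental QALYs across PSA draws,
#' with a 95% confidence ellipse and a willingness-to-pay reference line.
#' Requires ggplot2.
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay line, dollars per QALY.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 150000) {
  .need_ggplot()
  d <- psa$draws
  ggplot2::ggplot(d, ggplot2::aes(x = .data$d_qaly, y = .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::stat_ellipse(level = 0.95, colour = "firebrick") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_y_continuous(labels = function(x)
      paste0("$", format(x, big.mark = ",", scientific = FALSE))) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("WTP $%s/QALY (dashed)",
                                     format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param psa A `psa_result`.
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa) {
  .need_ggplot()
  d <- psa$ceac
  long <- rbind(
    data.frame(wtp = d$wtp, prop = d$prop_olaparib, strategy = "olaparib"),
    data.frame(wtp = d$wtp, prop = d$prop_no_olaparib,
               strategy = "no olaparib")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wtp, y = .data$prop,
                                     colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_continuous(labels = function(x)
      paste0("$", format(x, big.mark = ",", scientific = FALSE))) +
    ggplot2::labs(x = "Willingness to pay per QALY",
                  y = "Proportion of simulations preferred",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' @param tornado A `tornado` data frame from [one_way_sa()].
#' @param base_icer Base-case ICER, drawn as a vertical reference line.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, base_icer = NULL) {
  .need_ggplot()
  d <- as.data.frame(tornado)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  g <- ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 5, colour = "grey40") +
    ggplot2::scale_x_continuous(labels = function(x)
      paste0("$", format(x, big.mark = ",", scientific = FALSE))) +
    ggplot2::labs(x = "ICER per QALY", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
  if (!is.null(base_icer)) {
    g <- g + ggplot2::geom_vline(xintercept = base_icer,
                                 linetype = "dashed")
  }
  g
}

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
}

utils::globalVariables(".data")
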