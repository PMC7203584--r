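utils::globalVariables(c("bin", "pct_lf", "se", "direction", "block", "pi"))

#' Plot direction-split choice curves
#'
#' Percentage of LF choices per bin, split by sequence direction, with
#' standard-error bars: the direction gap in the mid-schedule bins is the
#' graphical signature of perseveration.
#'
#' @param curves Output of [perseveration_curves()].
#' @return A ggplot object.
#' @export
plot_perseveration_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(curves, ggplot2::aes(x = bin, y = pct_lf,
                                       colour = direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pct_lf - se,
                                          ymax = pct_lf + se)) +
    ggplot2::labs(x = "manipulation point / interval",
                  y = "% LF choices", colour = "direction") +
    ggplot2::theme_minimal()
}

#' Plot per-block perseveration-index distributions
#'
#' @param pi_df Output of [perseveration_indices()].
#' @return A ggplot object.
#' @export
plot_perseveration_index <- function(pi_df) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(pi_df, ggplot2::aes(x = block, y = pi)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "perseveration index") +
    ggplot2::theme_minimal()
}
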