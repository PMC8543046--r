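# Plotting helpers (ggplot2, Suggests-only).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
}

#' Histogram of element quality
#' @param quality a [quality_summary()] result.
#' @return a ggplot object.
#' @export
plot_quality <- function(quality) {
  .need_ggplot()
  df <- data.frame(knupp = quality$indices)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$knupp)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = quality$threshold, linetype = 2) +
    ggplot2::labs(x = "Knupp index (scaled Jacobian)", y = "elements",
                  title = sprintf("mean %.3f, %.1f%% below %.2f",
                                  quality$mean, 100 * quality$frac_below,
                                  quality$threshold)) +
    ggplot2::theme_minimal()
}

#' Distance ladder across correction stages
#' @param ladder a [distance_ladder_report()] data.frame.
#' @return a ggplot object.
#' @export
plot_ladder <- function(ladder) {
  .need_ggplot()
  ladder$stage <- factor(ladder$stage, levels = unique(ladder$stage))
  ggplot2::ggplot(ladder,
                  ggplot2::aes(x = .data$stage, y = .data$mean,
                               group = .data$label, colour = .data$label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "contour-to-mesh distance (mm)",
                  colour = "contour") +
    ggplot2::theme_minimal()
}
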