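#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a panel score table
#'
#' Conservative Signal Gain against conservative Signal Specificity Ratio,
#' one point per module; the dashed lines mark SG = 1 (no gain over the best
#' single gene) and SSR = 4 (a conventional specificity floor below which a
#' module risks misidentification).
#'
#' @param object A `panel_score` from [score_panel()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.panel_score <- function(object, ...) {
  df <- tidy(object)
  df$ssr_plot <- pmin(df$ssr_conservative, 10 * max(1, stats::median(
    df$ssr_conservative[is.finite(df$ssr_conservative)])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sg_conservative,
                                   y = .data$ssr_plot)) +
    ggplot2::geom_hline(yintercept = 4, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Signal Gain (conservative)",
                  y = "Signal Specificity Ratio (conservative)",
                  title = "Panel module scores")
}

#' Heatmap of a cell-by-module matrix
#'
#' Cells ordered by cluster (if given) against modules; the visual check that
#' modules light up coherent cell populations.
#'
#' @param object A `cell_by_module`.
#' @param clusters Optional [cluster_cells()] result used to order cells.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cell_by_module <- function(object, clusters = NULL, ...) {
  df <- tidy(object)
  if (!is.null(clusters)) {
    ord <- clusters$cell[order(clusters$cluster)]
    df$cell <- factor(df$cell, levels = ord)
    df <- df[df$cell %in% ord, ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$cell,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "module", y = "cell", fill = "intensity")
}

#' Box plot of neighbour counts around the two reference groups
#'
#' @param object A `proximity_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.proximity_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = .data$neighbor_count)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "reference group",
                  y = sprintf("query cells within %g µm",
                              object$radius_um),
                  subtitle = sprintf("fold-change %.2f, p = %.2g",
                                     object$fold_change, object$p_value))
}

#' Density of cells along the cortical depth
#'
#' @param depths Output of [cortical_depth()] or a numeric vector.
#' @param bandwidth Gaussian kernel standard deviation.
#' @return A ggplot.
#' @export
plot_depth_density <- function(depths, bandwidth = 0.05) {
  if (is.data.frame(depths)) depths <- depths$depth
  dd <- depth_density(depths, bandwidth = bandwidth)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$depth, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "normalized cortical depth", y = "cell density")
}
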