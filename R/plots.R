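# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cells in their section coordinates
#'
#' @param cells A `cell_tbl`.
#' @param colour Column name used for the point colour (default
#'   `subclass_label`).
#' @return A ggplot.
#' @export
plot_cells <- function(cells, colour = "subclass_label") {
  ggplot2::ggplot(as_tibble(cells)[setdiff(names(cells), c("counts", "imputed",
                                                           "composition"))],
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = factor(.data[[colour]]))) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = colour) +
    ggplot2::theme_minimal()
}

#' Plot spatial modules
#'
#' @param cells Output of [cluster_spatial_modules()].
#' @return A ggplot of cells coloured by module.
#' @export
plot_spatial_modules <- function(cells) plot_cells(cells, colour = "module")

#' Heatmap of an enrichment table
#'
#' @param object An `enrichment_tbl` from [enrichment_scores()].
#' @param ... Unused.
#' @return A ggplot tile map of log2 enrichment.
#' @export
autoplot.enrichment_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region, y = .data$type,
                                       fill = log2(.data$score + 1e-3))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "log2 fold") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Interaction-test overview
#'
#' Fold enrichment against observed proximal pairs, called pairs
#' highlighted.
#'
#' @param object An `interaction_tbl` from [test_interactions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interaction_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$observed, y = .data$fold,
                               colour = .data$called,
                               shape = .data$self_pair)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "observed proximal pairs", y = "fold vs null") +
    ggplot2::theme_minimal()
}

#' Confidence-score distributions of a label transfer
#'
#' @param object A `transfer_result` from [two_round_transfer()].
#' @param ... Unused.
#' @return A ggplot of subclass and cluster confidence histograms.
#' @export
autoplot.transfer_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("subclass_confidence", "cluster_confidence")],
    dplyr::everything(), names_to = "level", values_to = "confidence")
  gates <- attr(object, "gates") %||% c(subclass = 0.8, cluster = 0.5)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$confidence)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::facet_wrap(~level, scales = "free_y") +
    ggplot2::geom_vline(data = tibble(level = paste0(names(gates), "_confidence"),
                                      gate = unname(gates)),
                        ggplot2::aes(xintercept = .data$gate),
                        linetype = 2, colour = "firebrick") +
    ggplot2::theme_minimal()
}

#' Gradient correlation plot
#'
#' Gradient-axis score against the spatial coordinate with the Pearson r in
#' the subtitle.
#'
#' @param axis Output of [gradient_axis()].
#' @param coordinate The spatial coordinate used for orientation.
#' @return A ggplot.
#' @export
plot_gradient <- function(axis, coordinate) {
  df <- tibble(score = axis$score, coordinate = coordinate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coordinate, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick",
                         se = FALSE) +
    ggplot2::labs(subtitle = sprintf("Pearson r = %.3f", attr(axis, "r")),
                  x = "spatial coordinate",
                  y = paste0(attr(axis, "method"), " score")) +
    ggplot2::theme_minimal()
}
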