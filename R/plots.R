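#' Plot an RNA map profile
#'
#' Smoothed per-position motif coverage around the 3' splice site, one
#' line per group.
#'
#' @param object a `bs_rna_map` tibble from [rna_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bs_rna_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$smoothed,
                                       colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.7, na.rm = TRUE) +
    ggplot2::labs(x = "position relative to 3' splice site (nt)",
                  y = "motif coverage (fraction of events)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplot comparison of a feature between event groups
#'
#' Tukey boxes (outliers hidden, as in the published figure convention;
#' they are never excluded from the tests themselves).
#'
#' @param data tibble with the feature and grouping columns.
#' @param feature name of the numeric feature column.
#' @param group name of the grouping column.
#' @param log10_scale plot the feature on a log10 axis (for lengths).
#' @return a ggplot object.
#' @export
plot_feature_comparison <- function(data, feature, group = "group",
                                    log10_scale = FALSE) {
  stopifnot(feature %in% names(data), group %in% names(data))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data[[group]],
                                          y = .data[[feature]],
                                          fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  if (log10_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Scatter plot of splicing change magnitude against expression
#'
#' @param quantified tibble from [quantify_events()] (columns `delta`,
#'   `fpkm`).
#' @return a ggplot object annotated with the Pearson R.
#' @export
plot_expr_splicing <- function(quantified) {
  keep <- !is.na(quantified$delta) & !is.na(quantified$fpkm)
  d <- quantified[keep, ]
  r <- expr_splicing_correlation(abs(d$delta), d$fpkm)
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$fpkm + 1),
                                  y = abs(.data$delta))) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                      label = sprintf("R = %.3f", r$r)) +
    ggplot2::labs(x = "log10(FPKM + 1)", y = "|delta PSI/PIR| (%)") +
    ggplot2::theme_minimal()
}

#' Heatmap of delta values with hierarchical ordering
#'
#' @param delta_matrix numeric matrix, events x conditions.
#' @return a ggplot object (tiles, rows/columns ordered by
#'   [heatmap_order()]).
#' @export
plot_delta_heatmap <- function(delta_matrix) {
  ord <- heatmap_order(delta_matrix)
  m <- as.matrix(delta_matrix)[ord$kept, , drop = FALSE]
  m <- m[ord$row_order, ord$col_order, drop = FALSE]
  df <- tibble(
    event = factor(rep(rownames(m) %||% seq_len(nrow(m)), ncol(m)),
                   levels = rev(rownames(m) %||% seq_len(nrow(m)))),
    condition = factor(rep(colnames(m) %||% seq_len(ncol(m)),
                           each = nrow(m)),
                       levels = colnames(m) %||% seq_len(ncol(m))),
    delta = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$event,
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-100, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "delta (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
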