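#' Heatmap of a signal matrix or two-way clustering
#'
#' Draws the drug x event lnROR grid as a tile heatmap, red for high lnROR
#' (over-reporting relative to the comparator) through white near 0 to blue
#' for low. For a `two_way_cluster` the axes follow both dendrogram leaf
#' orders, so planted or discovered blocks appear contiguous.
#'
#' @param object A `signal_matrix` or `two_way_cluster`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_matrix <- function(object, ...) {
  plot_lnror_heatmap(object$lnror)
}

#' @rdname autoplot.signal_matrix
#' @export
autoplot.two_way_cluster <- function(object, ...) {
  plot_lnror_heatmap(object$matrix)
}

#' @rdname autoplot.signal_matrix
#' @param m A numeric lnROR matrix (drugs in rows, events in columns); row
#'   and column order is kept as given.
#' @export
plot_lnror_heatmap <- function(m) {
  df <- as.data.frame.table(as.matrix(m), responseName = "lnror",
                            stringsAsFactors = FALSE)
  names(df)[1:2] <- c("drug", "pt")
  df$drug <- factor(df$drug, levels = rev(rownames(m)))
  df$pt <- factor(df$pt, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pt, y = .data$drug,
                                   fill = .data$lnror)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, name = "lnROR") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' Dendrogram plot for a Ward tree
#'
#' @param tree A `ward_clust`.
#' @param ... Passed to `plot.hclust`.
#' @export
plot_dendrogram <- function(tree, ...) {
  plot(as.hclust(tree), ...)
}
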