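#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of normalised aggregated importance
#'
#' Tile plot of the naCLIFI matrix for the features with the largest absolute
#' normalised values, on a diverging scale with white at zero.
#'
#' @param table A `clifi_table`.
#' @param top_n Number of features shown, ranked by max |naCLIFI| over
#'   classes.
#' @return A ggplot object.
#' @export
plot_clifi_heatmap <- function(table, top_n = 10L) {
  stopifnot(inherits(table, "clifi_table"))
  score <- apply(abs(table$naclifi), 1L, max)
  keep <- names(sort(score, decreasing = TRUE))[seq_len(min(top_n,
                                                            length(score)))]
  df <- tibble::as_tibble(as.data.frame(table$naclifi[keep, , drop = FALSE]),
                          rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "class",
                        values_to = "naclifi")
  df$feature <- factor(df$feature, levels = rev(keep))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$feature,
                                   fill = .data$naclifi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "naCLIFI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Violin plot of split-level importance distributions
#'
#' Per-class distributions of the split-level CLIFI records for the selected
#' features; the spread away from zero indicates how strongly (and in which
#' direction) a feature drives each class.
#'
#' @param table A `clifi_table`.
#' @param features Character vector of feature names (default: all features
#'   with records).
#' @return A ggplot object, faceted by feature.
#' @export
plot_clifi_violin <- function(table, features = NULL) {
  stopifnot(inherits(table, "clifi_table"))
  df <- table$records
  if (!is.null(features)) df <- df[df$feature %in% features, ]
  if (nrow(df) == 0L) stop("no records for the requested features",
                           call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$class)) +
    ggplot2::geom_violin(scale = "width", trim = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(x = NULL, y = "CLIFI") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn plot_clifi_heatmap autoplot method; `type` selects
#'   `"heatmap"` (default) or `"violin"`.
#' @param object A `clifi_table`.
#' @param type Plot type.
#' @param ... Passed to the underlying plot function.
#' @method autoplot clifi_table
#' @export
autoplot.clifi_table <- function(object, type = c("heatmap", "violin"),
                                 ...) {
  type <- match.arg(type)
  if (type == "heatmap") plot_clifi_heatmap(object, ...) else
    plot_clifi_violin(object, ...)
}
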