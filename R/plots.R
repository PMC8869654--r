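#' Volcano plot of a differential-abundance result
#'
#' log2 ratio against -log10 p, colored by classification; sentinel-ratio
#' proteins (detected in one group only) are omitted with a message since
#' they have no finite fold change.
#'
#' @param object A `lfq_diff` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lfq_diff <- function(object, ...) {
  thr <- attr(object, "thresholds")
  df <- as_tibble(object)
  n_sent <- sum(df$detection != "both")
  if (n_sent) {
    inform(paste0(n_sent, " one-group-only proteins omitted from the volcano"))
  }
  df <- df[df$detection == "both", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = log2(.data$ratio), y = -log10(.data$p_value),
    colour = .data$classification
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(thr$alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log2(c(thr$down_cut, thr$up_cut)),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      up = "#c0392b", down = "#2471a3", unchanged = "grey60"
    )) +
    ggplot2::labs(
      x = "log2 fold change (case / control)",
      y = "-log10 Mann-Whitney p",
      colour = NULL,
      title = paste(attr(object, "case"), "vs", attr(object, "control"))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a z-scaled, clustered matrix
#'
#' @param object A `lfq_clustering` result from [zscale_cluster()].
#' @param ... Unused.
#' @return A ggplot tile heatmap with rows and columns in dendrogram leaf
#'   order.
#' @exportS3Method ggplot2::autoplot
autoplot.lfq_clustering <- function(object, ...) {
  long <- tidyr::pivot_longer(object$z, -"accession",
                              names_to = "sample_id", values_to = "z")
  long$accession <- factor(long$accession, levels = rev(object$row_order))
  long$sample_id <- factor(long$sample_id, levels = object$col_order)
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$accession,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2471a3", mid = "white",
                                  high = "#c0392b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Dot plot of enrichment results
#'
#' @param object A `lfq_enrichment` result.
#' @param top Show at most this many sets (by p-value).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lfq_enrichment <- function(object, top = 20, ...) {
  df <- head(as_tibble(object), top)
  df$set_name <- factor(df$set_name, levels = rev(df$set_name))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_adjusted), y = .data$set_name,
    size = .data$k, colour = .data$significant
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "-log10 BH-adjusted p", y = NULL,
                  size = "overlap", colour = "significant") +
    ggplot2::theme_minimal()
}
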