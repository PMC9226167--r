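# ggplot2 views of the main result types.

#' Plot per-sample diversity by group
#'
#' @param div Output of [diversity_metrics()].
#' @param metadata A data frame `sample_id`, `group`.
#' @param metric One of "richness", "shannon_h", "pielou_j", "chao1".
#' @return A ggplot object.
#' @export
plot_diversity <- function(div, metadata, metric = "richness") {
  vp_assert(metric %in% c("richness", "shannon_h", "pielou_j", "chao1"),
            "unknown diversity metric")
  df <- div |> left_join(metadata |> select(sample_id, group),
                         by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = group,
                                   y = .data[[metric]],
                                   fill = group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a PCoA ordination coloured by group
#'
#' @param ord A `virome_pcoa` from [pcoa()].
#' @param metadata A data frame `sample_id`, `group`.
#' @return A ggplot object.
#' @export
plot_pcoa <- function(ord, metadata) {
  df <- ord$coordinates |>
    left_join(metadata |> select(sample_id, group), by = "sample_id")
  ve <- round(100 * ord$variance_explained[1:2], 1)
  ggplot2::ggplot(df, ggplot2::aes(x = axis1, y = axis2,
                                   colour = group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", ve[1]),
                  y = sprintf("PCo2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
}

#' Plot cumulative ranked-abundance curves per sample
#'
#' @param layer Long abundance tibble with a unit id column, `sample_id`,
#'   `value`.
#' @param metadata Optional `sample_id`, `group` for colouring.
#' @return A ggplot object.
#' @export
plot_ranked_abundance <- function(layer, metadata = NULL) {
  unit_col <- intersect(c("vc_id", "unit_id", "contig_id"),
                        names(layer))[1]
  curves <- layer |>
    group_by(sample_id) |>
    dplyr::group_modify(function(d, g) {
      ranked_abundance_curve(d$value, d[[unit_col]])
    }) |>
    ungroup()
  if (!is.null(metadata)) {
    curves <- curves |>
      left_join(metadata |> select(sample_id, group), by = "sample_id")
    p <- ggplot2::ggplot(curves,
                         ggplot2::aes(x = abund_rank, y = cum_fraction,
                                      group = sample_id,
                                      colour = group))
  } else {
    p <- ggplot2::ggplot(curves,
                         ggplot2::aes(x = abund_rank, y = cum_fraction,
                                      group = sample_id))
  }
  p + ggplot2::geom_step(alpha = 0.6) +
    ggplot2::labs(x = "VC rank", y = "cumulative relative abundance") +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise shared-PC fractions
#'
#' @param m A matrix from [shared_pc_matrix()].
#' @param order_by_clustering Reorder rows/columns by average-linkage
#'   clustering of the rows.
#' @return A ggplot object.
#' @export
plot_shared_pc_heatmap <- function(m, order_by_clustering = TRUE) {
  if (order_by_clustering && nrow(m) > 2) {
    ord <- hclust(dist(m), method = "average")$order
    m <- m[ord, ord]
  }
  df <- as_tibble(as.data.frame.table(m, responseName = "value"))
  names(df)[1:2] <- c("a", "b")
  df$a <- factor(df$a, levels = rownames(m))
  df$b <- factor(df$b, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% shared PCs") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}
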