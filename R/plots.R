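#' Violin plots of node rank distributions by comparison group
#'
#' Mirrors the standard presentation of rank-shift results: per node, the
#' pooled rank values of each comparison group, optionally centred on the
#' ground-control mean so shifts read as deviations from zero.
#'
#' @param pooled A `kg_pooled`.
#' @param node_ids Nodes to show.
#' @param adjust Centre on the `GroundVsBaseline` mean first (default
#'   TRUE).
#' @return A ggplot object.
#' @export
plot_node_ranks <- function(pooled, node_ids, adjust = TRUE) {
  if (adjust) pooled <- adjust_ranks_by_baseline_mean(pooled)
  d <- dplyr::filter(tidy(pooled), .data$node_id %in% node_ids)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group_label, y = .data$rank,
                                  fill = .data$group_label)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.08, size = 0.8, alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$node_id), scales = "free_y") +
    ggplot2::labs(x = NULL,
                  y = if (adjust) "rank (ground-control centred)" else
                    "rank") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Scatter plot of gene fold-change scores
#'
#' x: averaged Welch t of spaceflight vs ground fold-change
#' distributions; y: log10 advantage of the combined spaceflight p-value
#' over the combined ground p-value.  Genes in the upper-right are
#' consistently and significantly shifted in spaceflight.
#'
#' @param scores Tibble from [score_gene_fc()].
#' @param label_top Number of genes (by |x| + |y|) to label (default 5).
#' @return A ggplot object.
#' @export
plot_gene_scores <- function(scores, label_top = 5) {
  d <- dplyr::filter(scores, !is.na(.data$x), !is.na(.data$y))
  lab <- d |>
    dplyr::arrange(dplyr::desc(abs(.data$x) + abs(.data$y))) |>
    utils::head(label_top)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$space_more_significant),
                        alpha = 0.8) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$gene_id),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "averaged Welch t (space vs ground fold changes)",
                  y = "log10 p advantage of spaceflight combination",
                  colour = "space more\nsignificant") +
    ggplot2::theme_minimal()
}

#' @describeIn select_top_nodes Plot per-type p-value distributions with
#'   top nodes highlighted.
#' @param object A `kg_topnodes`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.kg_topnodes <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("p_svb", "p_svg"), names_to = "contrast",
                        values_to = "p") |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::mutate(contrast = dplyr::recode(
      .data$contrast, p_svb = "Space vs Baseline",
      p_svg = "Space vs Ground"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$node_type, y = -log10(.data$p),
                                  colour = .data$top)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.7, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "-log10 p (Welch)", colour = "top node") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
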