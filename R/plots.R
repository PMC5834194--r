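#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-dataset fold changes of candidate lncRNAs
#'
#' Horizontal bars of log2 fold change, one panel per dataset, genes
#' ordered within each phenotype class by their mean absolute change --
#' the standard way candidate lists from this analysis are displayed.
#'
#' @param object An `lnc_candidates` table.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.lnc_candidates <- function(object, ...) {
  long <- tidy(object)
  long$gene_name <- factor(long$gene_name, levels = rev(unique(object$gene_name)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$log2fc, y = .data$gene_name,
                                     fill = .data$phenotype_class)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$phenotype_class),
                        cols = ggplot2::vars(.data$dataset),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = expression(log[2] ~ "fold change (treated / control)"),
                  y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot smooth- vs skeletal-muscle fold changes
#'
#' @param object An `lnc_cross_tissue` tibble.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.lnc_cross_tissue <- function(object, ...) {
  ggplot2::ggplot(object[object$direction != "not_comparable", ],
                  ggplot2::aes(x = .data$smooth_log2fc,
                               y = .data$skeletal_log2fc,
                               colour = .data$direction)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression("smooth muscle" ~ log[2] ~ "FC toward contractile"),
      y = expression("skeletal" ~ log[2] ~ "FC on differentiation"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot transcription-factor enrichment p-values
#'
#' @param object A `tf_enrichment` tibble.
#' @param p_cutoff Dashed reference line (default 0.1).
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.tf_enrichment <- function(object, p_cutoff = 0.1, ...) {
  d <- object[object$enriched_in == "synthetic_up", ]
  d$tf_name <- stats::reorder(d$tf_name, -d$p_one_sided)
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_one_sided),
                                  y = .data$tf_name)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = -log10(p_cutoff), linetype = 2) +
    ggplot2::labs(x = expression(-log[10] ~ "one-sided p"), y = NULL,
                  title = "TF peak enrichment in synthetic-up promoters") +
    ggplot2::theme_minimal()
}

#' Plot nearest-gene fold-change correlations
#'
#' @param object A `neighbor_pairs` tibble from [neighbor_correlation()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.neighbor_pairs <- function(object, ...) {
  d <- object[!is.na(object$correlation_r), ]
  d$lncrna_id <- stats::reorder(d$lncrna_id, d$correlation_r)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$correlation_r, y = .data$lncrna_id)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Pearson r of fold changes with nearest coding gene",
                  y = NULL) +
    ggplot2::xlim(-1, 1) +
    ggplot2::theme_minimal()
}
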