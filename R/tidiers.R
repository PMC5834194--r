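#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a candidate table
#'
#' Returns one row per (candidate, dataset) with the fold change and both
#' raw and BH-adjusted p-values in long form.
#'
#' @param x An `lnc_candidates` table.
#' @param ... Unused.
#'
#' @return A tibble: `gene_id`, `gene_name`, `phenotype_class`,
#'   `significant`, `dataset`, `log2fc`, `p_value`, `padj`.
#' @export
tidy.lnc_candidates <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = dplyr::matches("^(log2fc|p|padj)_"),
      names_to = c(".value", "dataset"),
      names_pattern = "^(log2fc|p|padj)_(.*)$"
    ) |>
    dplyr::rename(p_value = "p") |>
    dplyr::select("gene_id", "gene_name", "phenotype_class", "significant",
                  "dataset", "log2fc", "p_value", "padj")
}

#' Stage counts of a selection run
#'
#' @param x An `lnc_candidates` table.
#' @param ... Unused.
#'
#' @return A one-row tibble: genes in the shared universe, annotated
#'   lncRNAs among them, survivors of the abundance filter, concordant
#'   candidates per class, and the significant count.
#' @export
glance.lnc_candidates <- function(x, ...) {
  tibble::as_tibble(attr(x, "stage_counts"))
}

#' Tidy a TF-enrichment result
#'
#' @param x A `tf_enrichment` tibble.
#' @param ... Unused.
#'
#' @return The underlying tibble (one row per TF and tested direction).
#' @export
tidy.tf_enrichment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summary of a TF-enrichment run
#'
#' @param x A `tf_enrichment` tibble.
#' @param p_cutoff Highlighting threshold on the raw one-sided p (default
#'   0.1, the conventional reporting cutoff of this analysis).
#' @param ... Unused.
#'
#' @return A one-row tibble: number of TFs tested, and the number enriched
#'   below `p_cutoff` in each direction.
#' @export
glance.tf_enrichment <- function(x, p_cutoff = 0.1, ...) {
  tibble::tibble(
    n_tfs = length(unique(x$tf_name)),
    n_enriched_synthetic_up = sum(x$enriched_in == "synthetic_up" &
                                    x$p_one_sided < p_cutoff),
    n_enriched_contractile_up = sum(x$enriched_in == "contractile_up" &
                                      x$p_one_sided < p_cutoff)
  )
}
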