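#' Compare candidate lncRNAs against skeletal muscle differentiation
#'
#' For each smooth-muscle candidate, asks whether it moves in the same
#' direction during skeletal muscle (myoblast-to-myotube) differentiation.
#' The skeletal dataset is screened with the same criteria used for
#' selection -- abundance (`min_avg_fpkm`), fold-change magnitude
#' (`min_abs_log2fc`), the zero-denominator rule -- except that the t-test
#' cutoff is the relaxed single-dataset `p_skeletal`. Candidates passing the
#' screen are classified `same_direction` when the sign of their
#' smooth-muscle change toward the contractile phenotype matches the sign of
#' the skeletal change upon differentiation, `opposite_direction` otherwise;
#' all others (including genes absent from the skeletal data) are
#' `not_comparable`.
#'
#' @param candidates A candidate table from [select_candidates()].
#' @param skeletal An [expression_dataset()] with
#'   `treatment_direction = "toward_differentiated"`.
#' @param thresholds A [selection_thresholds()] list.
#'
#' @return A tibble of class `lnc_cross_tissue`: `gene_id`, `gene_name`,
#'   `phenotype_class`, `smooth_log2fc` (mean per-dataset change oriented so
#'   positive means toward contractile), `skeletal_log2fc`, `skeletal_p`,
#'   `direction`.
#' @export
cross_tissue_compare <- function(candidates, skeletal,
                                 thresholds = selection_thresholds()) {
  if (dataset_direction(skeletal) != "toward_differentiated") {
    rlang::abort("`skeletal` must have treatment_direction 'toward_differentiated'.")
  }
  lfc_cols <- grep("^log2fc_", names(candidates), value = TRUE)
  dirs <- attr(candidates, "datasets")
  smooth <- vapply(seq_len(nrow(candidates)), function(i) {
    lfc <- unlist(candidates[i, lfc_cols])
    ds <- sub("^log2fc_", "", lfc_cols)
    mean(orient_toward_contractile(lfc, unname(dirs[ds])))
  }, double(1))

  present <- candidates$gene_id %in% skeletal$gene_id
  sk <- tibble::tibble(gene_id = candidates$gene_id,
                       skeletal_log2fc = NA_real_, skeletal_p = NA_real_,
                       skeletal_ok = FALSE)
  if (any(present)) {
    ids <- candidates$gene_id[present]
    fct <- fold_change_table(skeletal, gene_ids = ids,
                             pseudocount = thresholds$pseudocount,
                             zero_fraction = thresholds$zero_fraction)
    all_samples <- c(attr(skeletal, "control_samples"),
                     attr(skeletal, "treated_samples"))
    mean_fpkm <- rowMeans(as.matrix(skeletal[match(ids, skeletal$gene_id),
                                             all_samples]))
    ok <- mean_fpkm >= thresholds$min_avg_fpkm &
      fct$denominator_valid &
      abs(fct$log2fc) > thresholds$min_abs_log2fc &
      !is.na(fct$p_value) & fct$p_value < thresholds$p_skeletal
    sk$skeletal_log2fc[present] <- fct$log2fc
    sk$skeletal_p[present] <- fct$p_value
    sk$skeletal_ok[present] <- ok
  }

  out <- tibble::tibble(
    gene_id = candidates$gene_id,
    gene_name = candidates$gene_name,
    phenotype_class = candidates$phenotype_class,
    smooth_log2fc = smooth,
    skeletal_log2fc = sk$skeletal_log2fc,
    skeletal_p = sk$skeletal_p,
    direction = dplyr::case_when(
      !sk$skeletal_ok ~ "not_comparable",
      sign(smooth) == sign(sk$skeletal_log2fc) ~ "same_direction",
      TRUE ~ "opposite_direction"
    )
  )
  class(out) <- unique(c("lnc_cross_tissue", class(out)))
  out
}
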