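# Per-dataset differential expression on the FPKM scale. The contrast is
# always treated over control, so the control group is the denominator of
# the fold change and the target of the zero-denominator rule.

# Welch two-sample two-tailed t-test p-value with a defined degenerate-case
# policy: groups with fewer than 2 samples give NA; when both groups have
# zero variance the p-value is 1 for equal means and NA (undefined)
# otherwise.
welch_p <- function(treated, control) {
  if (length(treated) < 2 || length(control) < 2) {
    return(NA_real_)
  }
  if (stats::var(treated) == 0 && stats::var(control) == 0) {
    return(if (mean(treated) == mean(control)) 1.0 else NA_real_)
  }
  stats::t.test(treated, control, var.equal = FALSE)$p.value
}

#' Per-gene fold changes and t-tests for one dataset
#'
#' Computes, for every gene (or a requested subset), the log2 fold change of
#' mean treated over mean control FPKM, the Welch two-tailed t-test p-value
#' between the two sample groups, and the zero-denominator validity flag:
#' the fold change is unusable when at least `zero_fraction` of the control
#' (denominator) samples are exactly 0.
#'
#' @param dataset An [expression_dataset()].
#' @param gene_ids Optional character vector restricting the genes.
#' @param pseudocount Added to both group means before the log2 ratio
#'   (default 0).
#' @param zero_fraction Zero-denominator rule threshold (default 0.5).
#'
#' @return A tibble with columns `gene_id`, `dataset`,
#'   `treatment_direction`, `mean_control`, `mean_treated`, `log2fc`,
#'   `p_value`, `denominator_valid`.
#' @export
fold_change_table <- function(dataset, gene_ids = NULL, pseudocount = 0,
                              zero_fraction = 0.5) {
  ctrl <- group_matrix(dataset, "control")
  trt <- group_matrix(dataset, "treated")
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, rownames(ctrl))
    if (length(missing) > 0) {
      rlang::abort(sprintf(
        "gene(s) absent from dataset '%s': %s", dataset_name(dataset),
        paste(utils::head(missing, 5), collapse = ", ")
      ))
    }
    ctrl <- ctrl[gene_ids, , drop = FALSE]
    trt <- trt[gene_ids, , drop = FALSE]
  }
  mean_control <- rowMeans(ctrl)
  mean_treated <- rowMeans(trt)
  log2fc <- log2((mean_treated + pseudocount) / (mean_control + pseudocount))
  p_value <- vapply(seq_len(nrow(ctrl)), function(i) {
    welch_p(trt[i, ], ctrl[i, ])
  }, double(1))
  n_degenerate <- sum(rowSums(ctrl != ctrl[, 1]) == 0 &
                        rowSums(trt != trt[, 1]) == 0)
  if (n_degenerate > 0) {
    rlang::warn(sprintf(
      "%d gene(s) in '%s' have zero variance in both groups; p-values set by the degenerate-case policy.",
      n_degenerate, dataset_name(dataset)
    ))
  }
  denominator_valid <- rowMeans(ctrl == 0) < zero_fraction
  ds_name <- dataset_name(dataset)
  ds_dir <- dataset_direction(dataset)
  tibble::tibble(
    gene_id = rownames(ctrl),
    dataset = ds_name,
    treatment_direction = ds_dir,
    mean_control = unname(mean_control),
    mean_treated = unname(mean_treated),
    log2fc = unname(log2fc),
    p_value = p_value,
    denominator_valid = unname(denominator_valid)
  )
}

#' Log2 fold change for a single gene
#'
#' Convenience wrapper around [fold_change_table()] for one gene.
#'
#' @inheritParams fold_change_table
#' @param gene_id A single gene id present in the dataset.
#'
#' @return A one-row tibble (see [fold_change_table()]).
#' @export
log2_fold_change <- function(dataset, gene_id, pseudocount = 0,
                             zero_fraction = 0.5) {
  stopifnot(length(gene_id) == 1)
  fold_change_table(dataset, gene_ids = gene_id, pseudocount = pseudocount,
                    zero_fraction = zero_fraction)
}

#' Zero-denominator rule
#'
#' A fold change is declared invalid when at least `zero_fraction` of the
#' samples in the denominator group have FPKM exactly 0. For the
#' treated-over-control fold changes reported by this package the
#' denominator group is the control group.
#'
#' @inheritParams log2_fold_change
#' @param which Which group is the denominator; default `"control"`.
#' @param zero_fraction Fraction of zero samples at or above which the rule
#'   fires (default 0.5).
#'
#' @return `TRUE` when the rule fires (fold change invalid).
#' @export
#'
#' @examples
#' ds <- expression_dataset(
#'   tibble::tibble(gene_id = "g", c1 = 0, c2 = 0, c3 = 1, c4 = 2,
#'                  t1 = 5, t2 = 6, t3 = 7, t4 = 8),
#'   "toy", c("c1", "c2", "c3", "c4"), c("t1", "t2", "t3", "t4"),
#'   "toward_synthetic"
#' )
#' zero_denominator_check(ds, "g")  # TRUE: 2/4 control samples are zero
zero_denominator_check <- function(dataset, gene_id,
                                   which = c("control", "treated"),
                                   zero_fraction = 0.5) {
  which <- match.arg(which)
  m <- group_matrix(dataset, which)
  if (!gene_id %in% rownames(m)) {
    rlang::abort(sprintf("gene '%s' absent from dataset '%s'", gene_id,
                         dataset_name(dataset)))
  }
  vals <- m[gene_id, ]
  mean(vals == 0) >= zero_fraction
}
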