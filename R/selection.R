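# Candidate selection: abundance filter -> per-dataset fold changes ->
# zero-denominator guard -> directional concordance across datasets ->
# tiered t-test significance. Fold-change signs are interpreted through each
# dataset's treatment_direction, so datasets pushing the phenotype in
# opposite directions can be combined.

#' Abundance filter over multiple datasets
#'
#' Removes low-expressed genes before fold-change analysis. Under the
#' default `"all"` policy a gene is removed iff its mean FPKM (over all
#' samples, both groups) is strictly below `min_avg_fpkm` in every dataset;
#' under `"any"` a single low dataset suffices for removal. The gene
#' universe is the intersection of the datasets' gene sets.
#'
#' @param datasets A list of [expression_dataset()] objects.
#' @param thresholds A [selection_thresholds()] list.
#' @param gene_ids Optional restriction of the gene universe.
#'
#' @return A tibble of retained genes: `gene_id` plus one `mean_fpkm_<name>`
#'   column per dataset.
#' @export
abundance_filter <- function(datasets, thresholds = selection_thresholds(),
                             gene_ids = NULL) {
  stopifnot(length(datasets) >= 1)
  universe <- Reduce(intersect, lapply(datasets, function(d) d$gene_id))
  if (!is.null(gene_ids)) universe <- intersect(universe, gene_ids)
  if (length(universe) == 0) {
    rlang::abort("empty gene universe: datasets share no gene ids.")
  }
  means <- vapply(datasets, function(d) {
    m <- as.matrix(d[match(universe, d$gene_id),
                     c(attr(d, "control_samples"), attr(d, "treated_samples"))])
    rowMeans(m)
  }, double(length(universe)))
  if (is.null(dim(means))) means <- matrix(means, nrow = length(universe))
  low <- means < thresholds$min_avg_fpkm
  removed <- if (thresholds$abundance_policy == "all") {
    rowSums(low) == ncol(low)
  } else {
    rowSums(low) > 0
  }
  out <- tibble::tibble(gene_id = universe)
  for (j in seq_along(datasets)) {
    out[[paste0("mean_fpkm_", dataset_name(datasets[[j]]))]] <- means[, j]
  }
  out[!removed, ]
}

# Orient a log2 fold change so that positive always means "toward the
# contractile/differentiated phenotype": fold changes from datasets whose
# treatment pushes toward the synthetic phenotype are sign-flipped.
orient_toward_contractile <- function(log2fc, treatment_direction) {
  ifelse(treatment_direction == "toward_synthetic", -log2fc, log2fc)
}

#' Directional concordance of fold changes across datasets
#'
#' Classifies each gene by requiring its fold change to point toward the
#' same phenotype in every dataset: `synthetic_up` needs
#' `log2fc > +min_abs_log2fc` in every toward-synthetic dataset and
#' `log2fc < -min_abs_log2fc` in every toward-contractile dataset;
#' `contractile_up` is the mirror image. Any dataset failing its strict
#' inequality, or any invalid denominator, yields `none`.
#'
#' @param records A fold-change tibble as returned by binding
#'   [fold_change_table()] rows over datasets; must contain `gene_id`,
#'   `dataset`, `treatment_direction`, `log2fc`, `denominator_valid`.
#' @param thresholds A [selection_thresholds()] list.
#' @param n_datasets Number of datasets every gene must be observed in;
#'   defaults to the number of distinct datasets present in `records`.
#'
#' @return A tibble with `gene_id`, `phenotype_class` (one of
#'   `"synthetic_up"`, `"contractile_up"`, `"none"`) and `reason` for
#'   unclassified genes.
#' @export
direction_concordance <- function(records, thresholds = selection_thresholds(),
                                  n_datasets = NULL) {
  need <- c("gene_id", "dataset", "treatment_direction", "log2fc",
            "denominator_valid")
  if (!all(need %in% names(records))) {
    rlang::abort("`records` must carry gene_id, dataset, treatment_direction, log2fc, denominator_valid.")
  }
  if (is.null(n_datasets)) n_datasets <- length(unique(records$dataset))
  thr <- thresholds$min_abs_log2fc
  records |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      all_valid = all(.data$denominator_valid),
      syn_ok = all(ifelse(.data$treatment_direction == "toward_synthetic",
                          .data$log2fc > thr, .data$log2fc < -thr)),
      con_ok = all(ifelse(.data$treatment_direction == "toward_synthetic",
                          .data$log2fc < -thr, .data$log2fc > thr)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      phenotype_class = dplyr::case_when(
        .data$n < n_datasets ~ NA_character_,
        !.data$all_valid ~ "none",
        .data$syn_ok ~ "synthetic_up",
        .data$con_ok ~ "contractile_up",
        TRUE ~ "none"
      ),
      reason = dplyr::case_when(
        .data$n < n_datasets ~ "missing_dataset",
        !.data$all_valid ~ "zero_denominator",
        .data$phenotype_class == "none" ~ "discordant",
        TRUE ~ NA_character_
      )
    ) |>
    (\(d) {
      if (anyNA(d$phenotype_class)) {
        rlang::abort("every gene needs one fold-change record per dataset.")
      }
      d
    })() |>
    dplyr::select("gene_id", "phenotype_class", "reason")
}

#' Tiered significance rule over per-dataset p-values
#'
#' A gene is labelled significant when its t-test p-value is below
#' `p_strict` in at least `n_strict` datasets and below `p_loose` in every
#' dataset. Undefined (NA) p-values fail both clauses.
#'
#' @param p_values Numeric vector, one p-value per dataset.
#' @param thresholds A [selection_thresholds()] list.
#'
#' @return A single logical.
#' @export
#'
#' @examples
#' significance_aggregate(c(0.05, 0.08, 0.20))  # TRUE
#' significance_aggregate(c(0.05, 0.08, 0.35))  # FALSE: loose bound violated
significance_aggregate <- function(p_values, thresholds = selection_thresholds()) {
  if (anyNA(p_values)) {
    return(FALSE)
  }
  sum(p_values < thresholds$p_strict) >= thresholds$n_strict &&
    all(p_values < thresholds$p_loose)
}

#' Select candidate lncRNAs by cross-dataset concordance
#'
#' End-to-end selection over two or more smooth-muscle differentiation
#' datasets with opposing treatment directions: restrict to annotated
#' lncRNAs, apply the abundance filter, compute per-dataset fold changes
#' and Welch t-tests, drop genes failing the zero-denominator rule,
#' classify directional concordance, and attach the tiered significance
#' label. Rows are sorted within each phenotype class by descending mean
#' absolute log2 fold change. A Benjamini-Hochberg adjusted p-value column
#' per dataset is reported for transparency but never gates selection.
#'
#' @param datasets List of [expression_dataset()] objects; at least two with
#'   opposing `treatment_direction`.
#' @param annotation An annotation tibble from [read_gtf()]; the gene
#'   universe is restricted to its `lncRNA` biotype. Pass `NULL` to skip the
#'   biotype restriction.
#' @param thresholds A [selection_thresholds()] list.
#'
#' @return A tibble of class `lnc_candidates`: `gene_id`, `gene_name`,
#'   one `log2fc_<dataset>`, `p_<dataset>` and `padj_<dataset>` column per
#'   dataset, `phenotype_class`, `mean_abs_log2fc`, `significant`. Stage
#'   counts are attached as the `stage_counts` attribute (see
#'   [glance.lnc_candidates()]).
#' @export
select_candidates <- function(datasets, annotation,
                              thresholds = selection_thresholds()) {
  dirs <- vapply(datasets, dataset_direction, character(1))
  if (!(any(dirs == "toward_synthetic") && any(dirs != "toward_synthetic")) ||
      length(datasets) < 2) {
    rlang::abort("need >= 2 datasets with opposing treatment directions.")
  }
  universe <- Reduce(intersect, lapply(datasets, function(d) d$gene_id))
  lnc_ids <- if (is.null(annotation)) {
    universe
  } else {
    intersect(universe, filter_biotype(annotation, "lncRNA")$gene_id)
  }
  if (length(lnc_ids) == 0) rlang::abort("no annotated lncRNAs in the datasets.")

  kept <- abundance_filter(datasets, thresholds, gene_ids = lnc_ids)

  fc <- dplyr::bind_rows(lapply(datasets, function(d) {
    fold_change_table(d, gene_ids = kept$gene_id,
                      pseudocount = thresholds$pseudocount,
                      zero_fraction = thresholds$zero_fraction)
  }))
  fc <- fc |>
    dplyr::group_by(.data$dataset) |>
    dplyr::mutate(padj = stats::p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup()

  classes <- direction_concordance(fc, thresholds,
                                   n_datasets = length(datasets))
  concordant <- classes[classes$phenotype_class != "none", ]

  sig <- fc |>
    dplyr::filter(.data$gene_id %in% concordant$gene_id) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      significant = significance_aggregate(.data$p_value, thresholds),
      mean_abs_log2fc = mean(abs(.data$log2fc)),
      .groups = "drop"
    )

  wide <- fc |>
    dplyr::filter(.data$gene_id %in% concordant$gene_id) |>
    dplyr::select("gene_id", "dataset", "log2fc", "p_value", "padj") |>
    tidyr::pivot_wider(
      names_from = "dataset",
      values_from = c("log2fc", "p_value", "padj"),
      names_glue = "{.value}_{dataset}"
    )
  names(wide) <- sub("^p_value_", "p_", names(wide))

  gene_names <- if (is.null(annotation)) {
    tibble::tibble(gene_id = concordant$gene_id,
                   gene_name = concordant$gene_id)
  } else {
    annotation[, c("gene_id", "gene_name")]
  }

  out <- concordant |>
    dplyr::select("gene_id", "phenotype_class") |>
    dplyr::left_join(gene_names, by = "gene_id") |>
    dplyr::left_join(wide, by = "gene_id") |>
    dplyr::left_join(sig, by = "gene_id") |>
    dplyr::relocate("gene_name", .after = "gene_id") |>
    dplyr::arrange(.data$phenotype_class, dplyr::desc(.data$mean_abs_log2fc),
                   .data$gene_id)

  structure(
    out,
    stage_counts = list(
      n_universe = length(universe),
      n_lncrna = length(lnc_ids),
      n_abundance = nrow(kept),
      n_synthetic_up = sum(out$phenotype_class == "synthetic_up"),
      n_contractile_up = sum(out$phenotype_class == "contractile_up"),
      n_significant = sum(out$significant)
    ),
    thresholds = thresholds,
    datasets = stats::setNames(dirs, vapply(datasets, dataset_name, character(1))),
    class = unique(c("lnc_candidates", class(out)))
  )
}
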