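# Orchestration: run the selection stage alone, or the whole analysis
# (cross-tissue comparison, promoter enrichment, neighbor correlation,
# ceRNA nomination) from a loaded or simulated study. Stages communicate
# only through the candidate table and the declared inputs; identical
# inputs and thresholds give identical outputs.

smooth_datasets <- function(study) {
  Filter(function(d) dataset_direction(d) != "toward_differentiated",
         study$datasets)
}

skeletal_dataset <- function(study) {
  sk <- Filter(function(d) dataset_direction(d) == "toward_differentiated",
               study$datasets)
  if (length(sk)) sk[[1]] else NULL
}

#' Run the candidate-selection stage
#'
#' Applies [select_candidates()] to the study's smooth-muscle datasets and
#' optionally writes `candidates.tsv` plus a machine-readable
#' `run_summary.json` with the per-stage counts and the thresholds used.
#'
#' @param study An `lnc_study` from [load_study()] or [simulate_study()].
#' @param thresholds A [selection_thresholds()] list.
#' @param out_dir Optional output directory.
#'
#' @return The `lnc_candidates` table, invisibly when writing.
#' @export
run_select <- function(study, thresholds = selection_thresholds(),
                       out_dir = NULL) {
  candidates <- select_candidates(smooth_datasets(study), study$annotation,
                                  thresholds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tibble::as_tibble(candidates),
                     file.path(out_dir, "candidates.tsv"))
    summary <- list(
      stage_counts = attr(candidates, "stage_counts"),
      thresholds = unclass(thresholds),
      datasets = as.list(attr(candidates, "datasets"))
    )
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(candidates))
  }
  candidates
}

#' Run the full analysis
#'
#' Selection followed by every downstream stage for which the study
#' provides inputs: skeletal cross-tissue comparison, promoter
#' transcription-factor enrichment (skipped with a message when either
#' candidate class is empty or no peaks are supplied), nearest-gene
#' fold-change correlation, and ceRNA nomination for the synthetic-up
#' candidates (which decrease upon differentiation). When `out_dir` is
#' given, each stage is written as a TSV next to a combined
#' `run_summary.json`.
#'
#' @inheritParams run_select
#' @param promoter_upstream,promoter_downstream Promoter window, bp around
#'   the TSS.
#'
#' @return A list of class `lnc_analysis` with elements `candidates`,
#'   `cross_tissue`, `enrichment`, `neighbors`, `cerna` (absent stages are
#'   `NULL`).
#' @export
run_full <- function(study, thresholds = selection_thresholds(),
                     out_dir = NULL, promoter_upstream = 2000,
                     promoter_downstream = 500) {
  candidates <- run_select(study, thresholds, out_dir = NULL)

  sk <- skeletal_dataset(study)
  cross <- if (!is.null(sk) && nrow(candidates) > 0) {
    cross_tissue_compare(candidates, sk, thresholds)
  }

  enrichment <- NULL
  if (!is.null(study$peaks) && nrow(candidates) > 0 &&
      all(c("synthetic_up", "contractile_up") %in% candidates$phenotype_class)) {
    cand_genes <- study$annotation[
      match(candidates$gene_id, study$annotation$gene_id), ]
    prom <- promoter_windows(cand_genes, promoter_upstream, promoter_downstream)
    inc <- peak_incidence(prom, study$peaks)
    enrichment <- tf_enrichment(
      inc, candidates[, c("gene_id", "phenotype_class")]
    )
  } else {
    rlang::inform("promoter enrichment skipped: need peaks and both candidate classes non-empty.")
  }

  neighbors <- if (nrow(candidates) > 0) {
    neighbor_correlation(candidates$gene_id, study$datasets,
                         study$annotation, thresholds)
  }

  cerna <- NULL
  if (!is.null(study$mirna_track) && !is.null(study$mirna_fc)) {
    down_ids <- candidates$gene_id[candidates$phenotype_class == "synthetic_up"]
    if (length(down_ids) > 0) {
      lnc <- study$annotation[study$annotation$gene_id %in% down_ids, ]
      cerna <- cerna_candidates(lnc, study$mirna_track,
                                "down_on_differentiation", study$mirna_fc)
    }
  }

  res <- structure(
    list(candidates = candidates, cross_tissue = cross,
         enrichment = enrichment, neighbors = neighbors, cerna = cerna),
    class = "lnc_analysis"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tibble::as_tibble(candidates),
                     file.path(out_dir, "candidates.tsv"))
    for (nm in c("cross_tissue", "enrichment", "neighbors", "cerna")) {
      if (!is.null(res[[nm]])) {
        readr::write_tsv(tibble::as_tibble(res[[nm]]),
                         file.path(out_dir, paste0(nm, ".tsv")))
      }
    }
    summary <- list(
      stage_counts = attr(candidates, "stage_counts"),
      thresholds = unclass(thresholds),
      n_same_direction = if (!is.null(cross)) sum(cross$direction == "same_direction"),
      n_opposite_direction = if (!is.null(cross)) sum(cross$direction == "opposite_direction"),
      n_enriched_tfs_p_below_0.1 = if (!is.null(enrichment)) {
        length(unique(enrichment$tf_name[enrichment$p_one_sided < 0.1]))
      },
      n_cerna_pairs = if (!is.null(cerna)) nrow(cerna)
    )
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.lnc_analysis <- function(x, ...) {
  sc <- attr(x$candidates, "stage_counts")
  cat("<lnc_analysis>\n")
  cat(sprintf("  candidates: %d synthetic_up + %d contractile_up (%d significant)\n",
              sc$n_synthetic_up, sc$n_contractile_up, sc$n_significant))
  if (!is.null(x$cross_tissue)) {
    cat(sprintf("  cross-tissue: %d same / %d opposite direction\n",
                sum(x$cross_tissue$direction == "same_direction"),
                sum(x$cross_tissue$direction == "opposite_direction")))
  }
  if (!is.null(x$enrichment)) {
    cat(sprintf("  enrichment: %d TF(s) with one-sided p < 0.1\n",
                length(unique(x$enrichment$tf_name[x$enrichment$p_one_sided < 0.1]))))
  }
  if (!is.null(x$neighbors)) {
    cat(sprintf("  neighbors: %d pairs, median r = %.2f\n",
                nrow(x$neighbors),
                stats::median(x$neighbors$correlation_r, na.rm = TRUE)))
  }
  if (!is.null(x$cerna)) {
    cat(sprintf("  ceRNA: %d retained (lncRNA, miRNA) pairs\n", nrow(x$cerna)))
  }
  invisible(x)
}
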