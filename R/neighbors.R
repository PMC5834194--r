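# The cis-acting hypothesis: a candidate lncRNA that regulates a nearby
# gene should show expression changes correlated with that gene's. We
# assign each lncRNA its nearest protein-coding gene (span-to-span gap,
# strand-agnostic) and correlate their log2 fold-change vectors across
# datasets/conditions.

#' Nearest protein-coding gene for each lncRNA
#'
#' Distance is the minimum gap between the two gene spans (0 when they
#' overlap or abut); strand and relative orientation are ignored. Ties are
#' broken by the smaller start coordinate, then lexicographic gene id.
#'
#' @param lncrnas,coding_genes Annotation tibbles (see [read_gtf()]); only
#'   `gene_id`, `chrom`, `start`, `end` are used. `coding_genes` is
#'   typically `filter_biotype(annotation, "protein_coding")`.
#'
#' @return A tibble `lncrna_id`, `neighbor_gene_id`, `distance_bp`;
#'   lncRNAs with no coding gene on their chromosome get `NA` neighbor.
#' @export
nearest_gene <- function(lncrnas, coding_genes) {
  purrr::map_dfr(seq_len(nrow(lncrnas)), function(i) {
    l <- lncrnas[i, ]
    cand <- coding_genes[coding_genes$chrom == l$chrom, ]
    if (nrow(cand) == 0) {
      return(tibble::tibble(lncrna_id = l$gene_id,
                            neighbor_gene_id = NA_character_,
                            distance_bp = NA_real_))
    }
    gap <- interval_gap(l$start, l$end, cand$start, cand$end)
    pick <- order(gap, cand$start, cand$gene_id)[1]
    tibble::tibble(lncrna_id = l$gene_id,
                   neighbor_gene_id = cand$gene_id[pick],
                   distance_bp = gap[pick])
  })
}

#' Pearson correlation of two fold-change vectors
#'
#' @param lnc_fc,nbr_fc Numeric vectors of log2 fold changes, aligned by
#'   condition; at least 3 points.
#'
#' @return The Pearson correlation coefficient, or `NA` when either vector
#'   has zero variance (correlation undefined).
#' @export
fold_change_correlation <- function(lnc_fc, nbr_fc) {
  if (length(lnc_fc) != length(nbr_fc) || length(lnc_fc) < 3) {
    rlang::abort("need >= 3 aligned fold-change points.")
  }
  if (anyNA(lnc_fc) || anyNA(nbr_fc) ||
      stats::sd(lnc_fc) == 0 || stats::sd(nbr_fc) == 0) {
    return(NA_real_)
  }
  stats::cor(lnc_fc, nbr_fc, method = "pearson")
}

#' Nearest-gene fold-change correlation for candidate lncRNAs
#'
#' Combines [nearest_gene()] with per-dataset fold changes: for each
#' lncRNA/neighbor pair the log2 fold changes across the supplied datasets
#' form the two vectors whose Pearson correlation is reported. Datasets in
#' which either gene fails the zero-denominator rule are dropped from the
#' pair's vector; pairs left with fewer than 3 points get `NA`.
#'
#' @param lncrna_ids Character vector of candidate lncRNA gene ids.
#' @param datasets List of [expression_dataset()] objects providing the
#'   fold-change conditions (three smooth-muscle sets plus the skeletal set
#'   gives the usual 4 points).
#' @param annotation Full annotation from [read_gtf()].
#' @param thresholds A [selection_thresholds()] list (pseudocount and
#'   zero-fraction are honoured).
#'
#' @return A tibble of class `neighbor_pairs`: `lncrna_id`,
#'   `neighbor_gene_id`, `distance_bp`, `correlation_r`, `n_points`.
#' @export
neighbor_correlation <- function(lncrna_ids, datasets, annotation,
                                 thresholds = selection_thresholds()) {
  lnc <- annotation[annotation$gene_id %in% lncrna_ids, ]
  coding <- filter_biotype(annotation, "protein_coding")
  pairs <- nearest_gene(lnc, coding)

  ids <- unique(c(pairs$lncrna_id,
                  pairs$neighbor_gene_id[!is.na(pairs$neighbor_gene_id)]))
  fc <- dplyr::bind_rows(lapply(datasets, function(d) {
    fold_change_table(d, gene_ids = intersect(ids, d$gene_id),
                      pseudocount = thresholds$pseudocount,
                      zero_fraction = thresholds$zero_fraction)
  }))

  stats_tbl <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    if (is.na(p$neighbor_gene_id)) {
      return(tibble::tibble(correlation_r = NA_real_, n_points = 0L))
    }
    lf <- fc[fc$gene_id == p$lncrna_id, ]
    nf <- fc[fc$gene_id == p$neighbor_gene_id, ]
    common <- intersect(lf$dataset, nf$dataset)
    lf <- lf[match(common, lf$dataset), ]
    nf <- nf[match(common, nf$dataset), ]
    use <- lf$denominator_valid & nf$denominator_valid &
      is.finite(lf$log2fc) & is.finite(nf$log2fc)
    if (sum(use) < 3) {
      return(tibble::tibble(correlation_r = NA_real_, n_points = sum(use)))
    }
    tibble::tibble(
      correlation_r = fold_change_correlation(lf$log2fc[use], nf$log2fc[use]),
      n_points = sum(use)
    )
  })

  out <- dplyr::bind_cols(pairs, stats_tbl)
  class(out) <- unique(c("neighbor_pairs", class(out)))
  out
}
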