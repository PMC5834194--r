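# ceRNA nomination: a candidate lncRNA that sponges a miRNA must carry
# predicted binding sites for it (miRcode-style target track intersected
# with the lncRNA exons) and the miRNA's expression must move inversely to
# the lncRNA's during differentiation.

#' Count miRNA binding sites within a lncRNA's exons
#'
#' For each miRNA (family) in the target track, counts the track intervals
#' overlapping at least one exon of each lncRNA by >= 1 bp. An interval
#' spanning an exon-intron boundary counts; one spanning two exons still
#' counts once. With `mode = "span"` the whole gene span is used instead of
#' the exons.
#'
#' @param lncrnas Annotation tibble rows for the lncRNAs of interest
#'   (needs `gene_id`, `chrom` and the `exons` list-column).
#' @param target_track Tibble of labelled intervals: `chrom`, `start`,
#'   `end`, `mirna_id`.
#' @param mode `"exon"` (default) or `"span"`.
#'
#' @return A tibble `lncrna_id`, `mirna_id`, `n_binding_sites` with one row
#'   per pair having at least one site.
#' @export
count_binding_sites <- function(lncrnas, target_track,
                                mode = c("exon", "span")) {
  mode <- match.arg(mode)
  stopifnot(all(c("chrom", "start", "end", "mirna_id") %in% names(target_track)))
  purrr::map_dfr(seq_len(nrow(lncrnas)), function(i) {
    g <- lncrnas[i, ]
    regions <- if (mode == "exon") {
      ex <- g$exons[[1]]
      tibble::tibble(chrom = g$chrom, start = ex$start, end = ex$end)
    } else {
      tibble::tibble(chrom = g$chrom, start = g$start, end = g$end)
    }
    track <- target_track[target_track$chrom == g$chrom, ]
    if (nrow(track) == 0) {
      return(tibble::tibble(lncrna_id = character(), mirna_id = character(),
                            n_binding_sites = integer()))
    }
    hit <- overlaps_any(track, regions)   # each site interval counted once
    if (!any(hit)) {
      return(tibble::tibble(lncrna_id = character(), mirna_id = character(),
                            n_binding_sites = integer()))
    }
    track[hit, ] |>
      dplyr::count(.data$mirna_id, name = "n_binding_sites") |>
      dplyr::mutate(lncrna_id = g$gene_id, .before = 1)
  })
}

#' Inverse-expression filter for ceRNA candidates
#'
#' Keeps only the (lncRNA, miRNA) pairs whose miRNA expression change
#' during differentiation is inverse to the lncRNA's: for a lncRNA that
#' decreases upon differentiation the miRNA's fold ratio must exceed 1 at
#' every provided time point; for an increasing lncRNA the mirror rule
#' (< 1 at every time point) applies. `mode = "any"` relaxes "every" to
#' "at least one" time point. miRNAs absent from the fold-ratio table are
#' dropped with a warning.
#'
#' @param candidates Tibble of pairs from [count_binding_sites()]
#'   (`lncrna_id`, `mirna_id`, `n_binding_sites`).
#' @param lncrna_direction Either a single direction applied to all
#'   lncRNAs, or a tibble `lncrna_id`, `direction`; directions are
#'   `"down_on_differentiation"` or `"up_on_differentiation"`.
#' @param mirna_fc Fold-ratio table: `mirna_id` plus one numeric column per
#'   time point (differentiated over undifferentiated ratios).
#' @param mode `"all"` (default: inverse at every time point) or `"any"`.
#'
#' @return A tibble of class `cerna_candidates`: the retained pairs with
#'   their fold-ratio columns and `passes_inverse_filter = TRUE`.
#' @export
inverse_expression_filter <- function(candidates, lncrna_direction, mirna_fc,
                                      mode = c("all", "any")) {
  mode <- match.arg(mode)
  dirs <- c("down_on_differentiation", "up_on_differentiation")
  if (is.character(lncrna_direction) && length(lncrna_direction) == 1) {
    lncrna_direction <- tibble::tibble(
      lncrna_id = unique(candidates$lncrna_id),
      direction = rlang::arg_match(lncrna_direction, dirs)
    )
  }
  stopifnot(all(lncrna_direction$direction %in% dirs))

  missing <- setdiff(unique(candidates$mirna_id), mirna_fc$mirna_id)
  if (length(missing) > 0) {
    rlang::warn(sprintf(
      "dropping %d miRNA(s) absent from the fold-ratio table: %s",
      length(missing), paste(missing, collapse = ", ")
    ))
    candidates <- candidates[!candidates$mirna_id %in% missing, ]
  }

  ratio_cols <- setdiff(names(mirna_fc), "mirna_id")
  out <- candidates |>
    dplyr::inner_join(lncrna_direction, by = "lncrna_id") |>
    dplyr::inner_join(mirna_fc, by = "mirna_id")
  ratios <- as.matrix(out[ratio_cols])
  up_rule <- ratios > 1     # miRNA increases on differentiation
  down_rule <- ratios < 1
  agg <- if (mode == "all") function(m) rowSums(!m) == 0 else function(m) rowSums(m) > 0
  passes <- ifelse(out$direction == "down_on_differentiation",
                   agg(up_rule), agg(down_rule))
  out$passes_inverse_filter <- as.logical(passes)
  out <- out[out$passes_inverse_filter, ]
  class(out) <- unique(c("cerna_candidates", class(out)))
  out
}

#' Nominate ceRNA candidates for a set of lncRNAs
#'
#' Composes [count_binding_sites()] and [inverse_expression_filter()].
#'
#' @inheritParams count_binding_sites
#' @inheritParams inverse_expression_filter
#'
#' @return A `cerna_candidates` tibble (see
#'   [inverse_expression_filter()]).
#' @export
cerna_candidates <- function(lncrnas, target_track, lncrna_direction,
                             mirna_fc, mode = c("all", "any"),
                             site_mode = c("exon", "span")) {
  sites <- count_binding_sites(lncrnas, target_track, mode = site_mode)
  if (nrow(sites) == 0) {
    out <- tibble::tibble(lncrna_id = character(), mirna_id = character(),
                          n_binding_sites = integer(),
                          passes_inverse_filter = logical())
    class(out) <- unique(c("cerna_candidates", class(out)))
    return(out)
  }
  inverse_expression_filter(sites, lncrna_direction, mirna_fc, mode = mode)
}
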