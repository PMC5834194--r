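# Promoter windows are defined relative to the gene's 5' end (TSS): 2,000 bp
# upstream through 500 bp downstream by default. In internal 0-based
# half-open coordinates a + strand gene with TSS t gets [t - up, t + down);
# a - strand gene gets the mirror image about its 5' base,
# [t - down + 1, t + up + 1). Both windows have length up + down and contain
# the TSS base.

#' Strand-aware promoter windows
#'
#' @param genes An annotation tibble (or subset) with `gene_id`, `chrom`,
#'   `strand`, `tss` columns; every gene must be stranded.
#' @param upstream_bp Bases upstream of the TSS (default 2000).
#' @param downstream_bp Bases downstream of the TSS, TSS base included
#'   (default 500).
#' @param chrom_lengths Optional named vector of chromosome lengths; windows
#'   are clipped to `[0, length)` when provided (and to 0 always).
#'
#' @return A tibble of class `promoter_windows`: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `clipped`.
#' @export
#'
#' @examples
#' g <- tibble::tibble(gene_id = "L1", chrom = "chr1", strand = "+", tss = 10000)
#' promoter_windows(g)  # [8000, 10500)
promoter_windows <- function(genes, upstream_bp = 2000, downstream_bp = 500,
                             chrom_lengths = NULL) {
  if (any(!genes$strand %in% c("+", "-"))) {
    bad <- genes$gene_id[!genes$strand %in% c("+", "-")][1]
    rlang::abort(sprintf("gene %s is unstranded: promoter undefined.", bad))
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream_bp, genes$tss - downstream_bp + 1)
  end <- ifelse(plus, genes$tss + downstream_bp, genes$tss + upstream_bp + 1)
  raw_start <- start
  raw_end <- end
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[genes$chrom])
    if (anyNA(lim)) {
      rlang::abort("chrom_lengths must cover every chromosome in `genes`.")
    }
    end <- pmin(end, lim)
  }
  out <- tibble::tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = start,
    end = end,
    strand = genes$strand,
    clipped = start != raw_start | end != raw_end
  )
  class(out) <- unique(c("promoter_windows", class(out)))
  out
}

#' Peak incidence of transcription factors in promoter windows
#'
#' Marks, for every (gene, TF) pair, whether at least one ChIP-seq peak of
#' that factor overlaps the gene's promoter window (>= 1 bp, half-open
#' semantics, strand ignored). Multiple peaks in one promoter still count as
#' a single incidence.
#'
#' @param promoters A [promoter_windows()] tibble.
#' @param peaks A tibble of peak intervals with columns `chrom`, `start`,
#'   `end`, `tf_name`.
#'
#' @return A tibble with `gene_id` plus one logical column per TF.
#' @export
peak_incidence <- function(promoters, peaks) {
  stopifnot(all(c("chrom", "start", "end", "tf_name") %in% names(peaks)))
  out <- tibble::tibble(gene_id = promoters$gene_id)
  for (tf in unique(peaks$tf_name)) {
    sub <- peaks[peaks$tf_name == tf, ]
    out[[tf]] <- overlaps_any(promoters, sub)
  }
  out
}

# One-sided hypergeometric tail probability that the "with-peak" count in
# the focal class is >= a, given the margins of the 2x2 table
#   a = focal with peak, b = focal without, c = other with, d = other without.
hypergeom_tail <- function(a, b, c, d) {
  stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Transcription-factor enrichment between candidate classes
#'
#' For each transcription factor, builds the 2x2 table of promoters with vs
#' without a peak, split by candidate class, and computes the one-sided
#' Fisher's exact (hypergeometric tail) probability that peaks are
#' over-represented in the promoters of the stated class. No multiplicity
#' correction is applied; raw p-values below 0.1 are conventionally
#' highlighted by the reporting stage.
#'
#' @param incidence A gene-by-TF incidence tibble from [peak_incidence()].
#' @param class_labels Tibble with `gene_id` and `phenotype_class`
#'   (`"synthetic_up"`/`"contractile_up"`); both classes must be non-empty.
#' @param alternative Class(es) to test for over-representation; by default
#'   both directions are reported.
#'
#' @return A tibble of class `tf_enrichment`: one row per (TF, direction)
#'   with `tf_name`, `enriched_in`, `a`, `b`, `c`, `d`, `p_one_sided`,
#'   where `a`/`b` count promoters of the tested class with/without a peak
#'   and `c`/`d` the other class.
#' @export
tf_enrichment <- function(incidence, class_labels,
                          alternative = c("synthetic_up", "contractile_up")) {
  alternative <- match.arg(alternative, several.ok = TRUE)
  lab <- class_labels[match(incidence$gene_id, class_labels$gene_id),
                      "phenotype_class", drop = TRUE]
  if (anyNA(lab)) rlang::abort("every gene in `incidence` needs a class label.")
  if (!all(c("synthetic_up", "contractile_up") %in% lab)) {
    rlang::abort("both candidate classes must be non-empty for enrichment testing.")
  }
  tfs <- setdiff(names(incidence), "gene_id")
  rows <- lapply(alternative, function(alt) {
    other <- setdiff(c("synthetic_up", "contractile_up"), alt)
    dplyr::bind_rows(lapply(tfs, function(tf) {
      hit <- incidence[[tf]]
      a <- sum(hit & lab == alt)
      b <- sum(!hit & lab == alt)
      c_ <- sum(hit & lab == other)
      d <- sum(!hit & lab == other)
      tibble::tibble(
        tf_name = tf, enriched_in = alt, a = a, b = b, c = c_, d = d,
        p_one_sided = hypergeom_tail(a, b, c_, d)
      )
    }))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$enriched_in,
                        .data$p_one_sided, .data$tf_name)
  class(out) <- unique(c("tf_enrichment", class(out)))
  out
}
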