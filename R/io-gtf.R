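#' Default mapping from annotation biotype strings to internal biotypes
#'
#' GENCODE-style `gene_type`/`gene_biotype` values are collapsed into the
#' four classes the pipeline distinguishes: `lncRNA`, `protein_coding`,
#' `miRNA_host` and `other`. Values absent from the map become `other` and
#' are ignored by all analysis stages.
#'
#' @return A named character vector mapping annotation values to internal
#'   biotypes.
#' @export
default_biotype_map <- function() {
  c(
    lncRNA = "lncRNA",
    lincRNA = "lncRNA",
    antisense = "lncRNA",
    antisense_RNA = "lncRNA",
    processed_transcript = "lncRNA",
    sense_intronic = "lncRNA",
    sense_overlapping = "lncRNA",
    protein_coding = "protein_coding",
    miRNA_host = "miRNA_host",
    other = "other"
  )
}

#' Read a gene annotation from GTF
#'
#' Parses a 9-column GTF (GENCODE dialect: `gene_id`, `gene_name` and
#' `gene_type`/`gene_biotype` attributes are honoured) into a gene-level
#' annotation tibble. GTF coordinates are 1-based inclusive; they are
#' converted to the package-internal 0-based half-open convention at this
#' boundary. Multi-transcript genes are collapsed to their gene span and the
#' union of their exons; genes without exon records get a single exon equal
#' to the span. The transcription start site (`tss`) is the 0-based
#' coordinate of the gene's 5' base: `start` on the + strand, `end - 1` on
#' the - strand.
#'
#' @param path Path to a GTF file.
#' @param biotype_map Named character vector mapping annotation biotype
#'   strings to internal biotypes; see [default_biotype_map()]. Unmapped
#'   values become `"other"`.
#' @param genome_build Label stored on the result (e.g. `"hg19"`).
#'
#' @return A tibble of class `lnc_annotation` with one row per gene and
#'   columns `gene_id`, `gene_name`, `biotype`, `chrom`, `start`, `end`,
#'   `strand`, `tss` and a list-column `exons` (each element a tibble with
#'   `start`, `end`).
#' @export
read_gtf <- function(path, biotype_map = default_biotype_map(),
                     genome_build = NA_character_) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("GTF file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  body <- which(nzchar(lines) & !startsWith(lines, "#"))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nfield != 9L)) {
    bad <- body[which(nfield != 9L)[1]]
    rlang::abort(sprintf(
      "malformed GTF line %d in %s: expected 9 tab-separated fields, got %d",
      bad, path, nfield[which(nfield != 9L)[1]]
    ))
  }
  if (length(body) == 0L) {
    rlang::abort(sprintf("GTF file has no feature lines: %s", path))
  }

  gr <- rtracklayer::import(path, format = "gtf")
  df <- tibble::as_tibble(as.data.frame(gr))
  if (!"gene_id" %in% names(df)) {
    rlang::abort("GTF attributes must include gene_id.")
  }
  if (!"gene_name" %in% names(df)) df$gene_name <- df$gene_id
  raw_bt <- if ("gene_type" %in% names(df)) {
    df$gene_type
  } else if ("gene_biotype" %in% names(df)) {
    df$gene_biotype
  } else {
    rep(NA_character_, nrow(df))
  }
  mapped <- unname(biotype_map[raw_bt])
  mapped[is.na(mapped)] <- "other"

  df <- dplyr::mutate(
    df,
    chrom = as.character(.data$seqnames),
    start0 = .data$start - 1,       # GTF 1-based inclusive -> 0-based half-open
    end0 = as.double(.data$end),
    strand = as.character(.data$strand),
    biotype = mapped
  )

  per_gene <- df |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(function(g, key) {
      strands <- unique(g$strand)
      if (length(strands) > 1) {
        rlang::abort(sprintf(
          "gene %s has records on mixed strands (%s)",
          key$gene_id, paste(strands, collapse = ", ")
        ))
      }
      gene_rec <- g[g$type == "gene", , drop = FALSE]
      exon_rec <- g[g$type == "exon", , drop = FALSE]
      span_start <- if (nrow(gene_rec)) min(gene_rec$start0) else min(g$start0)
      span_end <- if (nrow(gene_rec)) max(gene_rec$end0) else max(g$end0)
      exons <- if (nrow(exon_rec)) {
        merge_intervals(tibble::tibble(start = exon_rec$start0, end = exon_rec$end0))
      } else {
        tibble::tibble(start = span_start, end = span_end)
      }
      if (any(exons$start < span_start | exons$end > span_end)) {
        rlang::abort(sprintf("gene %s has exons outside its span", key$gene_id))
      }
      tibble::tibble(
        gene_id = key$gene_id,
        gene_name = g$gene_name[1],
        biotype = g$biotype[1],
        chrom = g$chrom[1],
        start = span_start,
        end = span_end,
        strand = strands,
        tss = if (strands == "-") span_end - 1 else span_start,
        exons = list(exons)
      )
    }) |>
    dplyr::bind_rows()

  new_annotation(per_gene, genome_build = genome_build)
}

new_annotation <- function(genes, genome_build = NA_character_) {
  if (anyDuplicated(genes$gene_id)) {
    rlang::abort("gene_ids must be unique in an annotation.")
  }
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  attr(genes, "genome_build") <- genome_build
  class(genes) <- unique(c("lnc_annotation", class(tibble::tibble())))
  genes
}

#' Write a gene annotation as GTF
#'
#' Inverse of [read_gtf()]: emits one `gene` line and one `exon` line per
#' exon for every gene, converting internal 0-based half-open coordinates
#' back to 1-based inclusive GTF coordinates. `read_gtf(write_gtf(x))`
#' reproduces all coordinates exactly.
#'
#' @param annotation An annotation tibble as returned by [read_gtf()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  fmt_line <- function(chrom, type, start0, end0, strand, gid, gname, bt) {
    sprintf(
      "%s\tlncswitch\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\"; gene_type \"%s\";",
      chrom, type, as.integer(start0 + 1), as.integer(end0), strand, gid, gname, bt
    )
  }
  lines <- unlist(lapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    ex <- g$exons[[1]]
    c(
      fmt_line(g$chrom, "gene", g$start, g$end, g$strand, g$gene_id, g$gene_name, g$biotype),
      vapply(seq_len(nrow(ex)), function(j) {
        fmt_line(g$chrom, "exon", ex$start[j], ex$end[j], g$strand, g$gene_id,
                 g$gene_name, g$biotype)
      }, character(1))
    )
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Subset an annotation by biotype
#'
#' @param annotation An annotation tibble from [read_gtf()].
#' @param biotype Internal biotype(s) to keep, e.g. `"lncRNA"`.
#'
#' @return The filtered annotation tibble.
#' @export
filter_biotype <- function(annotation, biotype) {
  annotation[annotation$biotype %in% biotype, ]
}
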