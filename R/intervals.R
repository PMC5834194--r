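# Genomic intervals are kept in the BED convention throughout the package:
# 0-based start, exclusive end, half-open [start, end). GTF input is converted
# at the boundary by read_gtf(). An interval tibble has at least the columns
# chrom, start, end; strand ("+", "-", "*") and name are optional.

#' Construct a tibble of genomic intervals
#'
#' Light validating constructor for the interval tables used across the
#' package (promoter windows, ChIP-seq peaks, miRNA target sites).
#' Coordinates are 0-based half-open.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions; must satisfy `start < end`.
#' @param strand Optional strand, one of `"+"`, `"-"`, `"*"` (unstranded).
#' @param name Optional label (e.g. a transcription factor or miRNA id).
#'
#' @return A tibble with columns `chrom`, `start`, `end` and, when supplied,
#'   `strand` and `name`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, name = NULL) {
  start <- as.double(start)
  end <- as.double(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    rlang::abort("`chrom` must be non-empty chromosome names.")
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "invalid interval at position %d: need 0 <= start < end (got [%s, %s))",
      bad[1], format(start[bad[1]]), format(end[bad[1]])
    ))
  }
  out <- tibble::tibble(chrom = as.character(chrom), start = start, end = end)
  if (!is.null(strand)) {
    if (!all(strand %in% c("+", "-", "*"))) {
      rlang::abort("`strand` values must be '+', '-' or '*'.")
    }
    out$strand <- strand
  }
  if (!is.null(name)) out$name <- as.character(name)
  out
}

#' Pairwise overlap of genomic intervals
#'
#' Half-open overlap test: two intervals overlap iff they share a chromosome
#' and `a.start < b.end & b.start < a.end`. Strand is ignored. `x` and `y`
#' are matched row-by-row (recycled if one has a single row), as in
#' arithmetic on vectors.
#'
#' @param x,y Interval tibbles with columns `chrom`, `start`, `end`.
#'
#' @return A logical vector, one element per compared pair.
#' @export
#'
#' @examples
#' a <- genomic_intervals("chr1", 10, 20)
#' b <- genomic_intervals("chr1", 20, 30)
#' intervals_overlap(a, b)  # FALSE: abutting half-open intervals do not overlap
intervals_overlap <- function(x, y) {
  n <- max(nrow(x), nrow(y))
  if (nrow(x) != n) x <- x[rep_len(seq_len(nrow(x)), n), ]
  if (nrow(y) != n) y <- y[rep_len(seq_len(nrow(y)), n), ]
  x$chrom == y$chrom & x$start < y$end & y$start < x$end
}

# For each row of `query`, how many rows of `subject` overlap it.
count_overlapping <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    sum(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          query$start[i] < subject$end)
  }, integer(1))
}

# For each row of `query`, TRUE iff any row of `subject` overlaps it.
overlaps_any <- function(query, subject) {
  count_overlapping(query, subject) > 0L
}

# Gap in bp between two spans on the same chromosome; 0 when they overlap
# or abut. Vectorised.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start2 - end1, start1 - end2))
}

# Merge overlapping/abutting intervals (start/end columns, one chromosome).
# Used to collapse the exon union of a multi-transcript gene.
merge_intervals <- function(df) {
  if (nrow(df) <= 1) {
    return(df[order(df$start), c("start", "end")])
  }
  df <- df[order(df$start, df$end), ]
  starts <- df$start
  ends <- df$end
  keep_start <- starts[1]
  out_start <- out_end <- numeric(0)
  cur_end <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_end) {
      cur_end <- max(cur_end, ends[i])
    } else {
      out_start <- c(out_start, keep_start)
      out_end <- c(out_end, cur_end)
      keep_start <- starts[i]
      cur_end <- ends[i]
    }
  }
  tibble::tibble(start = c(out_start, keep_start), end = c(out_end, cur_end))
}
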