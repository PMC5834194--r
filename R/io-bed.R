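#' Read genomic intervals from a BED file
#'
#' Accepts BED3 up to BED6. BED coordinates are already 0-based half-open and
#' are preserved exactly. The name column, when present, is kept as `name`
#' (used for transcription-factor or miRNA-family labels); duplicated
#' intervals are kept.
#'
#' @param path Path to a BED file (plain text, tab-separated).
#'
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`. An empty file yields a zero-row
#'   tibble.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("BED file not found: %s", path))
  }
  empty <- tibble::tibble(
    chrom = character(), start = double(), end = double(), name = character()
  )
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3L)) {
    rlang::abort(sprintf(
      "malformed BED line %d in %s: fewer than 3 fields", which(nf < 3L)[1], path
    ))
  }
  get_col <- function(k) vapply(fields, function(f) {
    if (length(f) >= k) f[k] else NA_character_
  }, character(1))
  out <- tibble::tibble(
    chrom = get_col(1),
    start = suppressWarnings(as.double(get_col(2))),
    end = suppressWarnings(as.double(get_col(3)))
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1]
    rlang::abort(sprintf("non-numeric BED coordinate at line %d in %s", bad, path))
  }
  bad <- which(out$start >= out$end | out$start < 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "invalid BED interval at line %d in %s: need 0 <= start < end", bad[1], path
    ))
  }
  if (max(nf) >= 4L) out$name <- get_col(4)
  if (max(nf) >= 5L) out$score <- suppressWarnings(as.double(get_col(5)))
  if (max(nf) >= 6L) out$strand <- get_col(6)
  out
}

#' Write genomic intervals to BED
#'
#' @param intervals Interval tibble with `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand` columns.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  has <- function(col) col %in% names(intervals)
  cols <- list(
    intervals$chrom,
    format(intervals$start, scientific = FALSE, trim = TRUE),
    format(intervals$end, scientific = FALSE, trim = TRUE)
  )
  if (has("name")) {
    cols <- c(cols, list(intervals$name))
    if (has("score")) {
      cols <- c(cols, list(format(intervals$score, trim = TRUE)))
      if (has("strand")) cols <- c(cols, list(intervals$strand))
    } else if (has("strand")) {
      cols <- c(cols, list(rep("0", nrow(intervals)), intervals$strand))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}
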