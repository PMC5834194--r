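# An expression dataset is a tibble with a gene_id column followed by one
# numeric FPKM column per sample, plus attributes describing the contrast:
#   name                dataset label
#   control_samples     sample ids of the untreated/undifferentiated group
#   treated_samples     sample ids of the treated/differentiated group
#   treatment_direction "toward_synthetic", "toward_contractile" or
#                       "toward_differentiated" -- the phenotype the
#                       treatment pushes the cells toward (PDGF pushes
#                       VSMCs toward synthetic; MYOCD/TGF-beta toward
#                       contractile; low serum differentiates myoblasts).

TREATMENT_DIRECTIONS <- c("toward_synthetic", "toward_contractile",
                          "toward_differentiated")

#' Construct an expression dataset
#'
#' @param fpkm A tibble/data.frame with a `gene_id` column and one
#'   non-negative numeric FPKM column per sample.
#' @param name Dataset label (e.g. `"smooth_synthetic"`).
#' @param control_samples,treated_samples Disjoint, non-empty character
#'   vectors of sample column names.
#' @param treatment_direction One of `"toward_synthetic"`,
#'   `"toward_contractile"`, `"toward_differentiated"`.
#'
#' @return A tibble of class `expression_dataset` carrying the grouping as
#'   attributes.
#' @export
expression_dataset <- function(fpkm, name, control_samples, treated_samples,
                               treatment_direction) {
  fpkm <- tibble::as_tibble(fpkm)
  if (!"gene_id" %in% names(fpkm)) {
    rlang::abort("`fpkm` must have a gene_id column.")
  }
  treatment_direction <- rlang::arg_match(treatment_direction,
                                          TREATMENT_DIRECTIONS)
  samples <- setdiff(names(fpkm), "gene_id")
  missing <- setdiff(c(control_samples, treated_samples), samples)
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "samples in the manifest are missing from the table: %s",
      paste(missing, collapse = ", ")
    ))
  }
  if (length(control_samples) == 0 || length(treated_samples) == 0 ||
      length(intersect(control_samples, treated_samples)) > 0) {
    rlang::abort("control and treated sample sets must be disjoint and non-empty.")
  }
  vals <- as.matrix(fpkm[samples])
  if (!is.numeric(vals)) rlang::abort("FPKM columns must be numeric.")
  if (anyNA(vals)) rlang::abort("FPKM values must not be missing.")
  if (any(vals < 0)) rlang::abort("FPKM values must be non-negative.")
  if (anyDuplicated(fpkm$gene_id)) rlang::abort("gene_ids must be unique.")
  structure(
    fpkm,
    name = name,
    control_samples = control_samples,
    treated_samples = treated_samples,
    treatment_direction = treatment_direction,
    class = unique(c("expression_dataset", class(fpkm)))
  )
}

dataset_name <- function(dataset) attr(dataset, "name")
dataset_direction <- function(dataset) attr(dataset, "treatment_direction")

# FPKM sub-matrix (genes x samples) for one group, rownames = gene_id.
group_matrix <- function(dataset, which = c("control", "treated")) {
  which <- match.arg(which)
  cols <- attr(dataset, paste0(which, "_samples"))
  m <- as.matrix(dataset[cols])
  rownames(m) <- dataset$gene_id
  m
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset '%s'> %d genes; %d control + %d treated samples; %s\n",
    dataset_name(x), nrow(x), length(attr(x, "control_samples")),
    length(attr(x, "treated_samples")), dataset_direction(x)
  ))
  NextMethod()
}

#' Read a Cuffnorm-style FPKM table
#'
#' Expects a tab-separated table with a header row of sample ids and a first
#' column of gene ids, as produced by Cuffnorm and similar quantifiers.
#'
#' @param path Path to the table.
#' @param name Dataset label.
#' @param control_samples,treated_samples Sample ids assigned to each group;
#'   every id must appear in the header.
#' @param treatment_direction See [expression_dataset()].
#'
#' @return An `expression_dataset` tibble.
#' @export
read_expression_table <- function(path, name, control_samples, treated_samples,
                                  treatment_direction) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("expression table not found: %s", path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  names(tab)[1] <- "gene_id"
  for (col in setdiff(names(tab), "gene_id")) {
    num <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(num) && !all(is.na(tab[[col]][is.na(num)]))) {
      bad <- which(is.na(num) & !is.na(tab[[col]]))[1]
      rlang::abort(sprintf(
        "non-numeric cell in %s: column '%s', data row %d ('%s')",
        path, col, bad, tab[[col]][bad]
      ))
    }
    tab[[col]] <- num
  }
  expression_dataset(tab, name, control_samples, treated_samples,
                     treatment_direction)
}

#' Write an expression dataset as a tab-separated FPKM table
#'
#' @param dataset An `expression_dataset`.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(dataset, path) {
  tab <- tibble::as_tibble(dataset)
  num <- setdiff(names(tab), "gene_id")
  tab[num] <- lapply(tab[num], function(x) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Load a full study from a manifest
#'
#' Reads the YAML manifest written by [write_study()] (or hand-written in the
#' same shape) and loads the annotation, every expression dataset, the
#' ChIP-seq peaks, the miRNA target track and the miRNA fold-ratio table.
#'
#' @param manifest_path Path to a `manifest.yaml`; relative paths inside the
#'   manifest are resolved against its directory.
#'
#' @return A list of class `lnc_study` with elements `annotation`,
#'   `datasets` (named list of `expression_dataset`), `peaks`,
#'   `mirna_track`, `mirna_fc`.
#' @export
load_study <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    rlang::abort(sprintf("manifest not found: %s", manifest_path))
  }
  man <- yaml::read_yaml(manifest_path)
  root <- dirname(manifest_path)
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(root, p)

  annotation <- read_gtf(resolve(man$annotation))
  datasets <- lapply(man$datasets, function(d) {
    read_expression_table(
      resolve(d$path), d$name,
      control_samples = unlist(d$control_samples),
      treated_samples = unlist(d$treated_samples),
      treatment_direction = d$treatment_direction
    )
  })
  names(datasets) <- vapply(man$datasets, `[[`, character(1), "name")

  peaks <- if (!is.null(man$peaks)) {
    p <- read_bed(resolve(man$peaks))
    if (is.null(p$name)) rlang::abort("peak BED must carry the TF in the name column.")
    dplyr::rename(p, tf_name = "name")
  }
  mirna_track <- if (!is.null(man$mirna_track)) {
    tr <- read_bed(resolve(man$mirna_track))
    if (is.null(tr$name)) rlang::abort("target track BED must carry the miRNA id in the name column.")
    dplyr::rename(tr, mirna_id = "name")
  }
  mirna_fc <- if (!is.null(man$mirna_fold_ratios)) {
    readr::read_tsv(resolve(man$mirna_fold_ratios),
                    col_types = readr::cols(
                      mirna_id = readr::col_character(),
                      .default = readr::col_double()
                    ))
  }
  structure(
    list(annotation = annotation, datasets = datasets, peaks = peaks,
         mirna_track = mirna_track, mirna_fc = mirna_fc),
    class = "lnc_study"
  )
}
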