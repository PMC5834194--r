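#' Selection thresholds for the concordance pipeline
#'
#' Bundles every tunable cutoff of the candidate-selection procedure with
#' the study defaults. All thresholds act on FPKM-scale expression or on
#' raw (uncorrected) t-test p-values.
#'
#' @param min_avg_fpkm Abundance floor: a gene is removed when its mean FPKM
#'   is strictly below this value in every dataset (`abundance_policy =
#'   "all"`, the default) or in any dataset (`"any"`). Default 5.
#' @param min_abs_log2fc Strict fold-change cutoff: a dataset only counts
#'   toward concordance when `|log2fc|` exceeds this value. Default 0.5.
#' @param zero_fraction A fold change is invalidated when at least this
#'   fraction of the denominator (control) group's samples have FPKM exactly
#'   0. Default 0.5.
#' @param p_strict,n_strict,p_loose Tiered significance rule: a candidate is
#'   labelled significant when its t-test p-value is `< p_strict` in at
#'   least `n_strict` datasets and `< p_loose` in all datasets. Defaults
#'   0.1, 2, 0.3.
#' @param p_skeletal Relaxed p-value cutoff used when the same selection is
#'   applied to the single skeletal-muscle differentiation dataset.
#'   Default 0.2.
#' @param abundance_policy `"all"` (remove genes low in all datasets,
#'   literal reading of the filter) or `"any"` (remove genes low in any).
#' @param pseudocount Added to both group means before taking the log2
#'   ratio. Default 0; the zero-denominator rule is the guard against
#'   division by zero.
#'
#' @return A list of class `selection_thresholds`.
#' @export
selection_thresholds <- function(min_avg_fpkm = 5,
                                 min_abs_log2fc = 0.5,
                                 zero_fraction = 0.5,
                                 p_strict = 0.1,
                                 n_strict = 2L,
                                 p_loose = 0.3,
                                 p_skeletal = 0.2,
                                 abundance_policy = c("all", "any"),
                                 pseudocount = 0) {
  abundance_policy <- match.arg(abundance_policy)
  th <- list(
    min_avg_fpkm = min_avg_fpkm, min_abs_log2fc = min_abs_log2fc,
    zero_fraction = zero_fraction, p_strict = p_strict,
    n_strict = as.integer(n_strict), p_loose = p_loose,
    p_skeletal = p_skeletal, abundance_policy = abundance_policy,
    pseudocount = pseudocount
  )
  num <- unlist(th[c("min_avg_fpkm", "min_abs_log2fc", "zero_fraction",
                     "p_strict", "n_strict", "p_loose", "p_skeletal",
                     "pseudocount")])
  if (any(num < 0)) rlang::abort("all thresholds must be >= 0.")
  if (th$p_strict > th$p_loose) {
    rlang::abort("p_strict must not exceed p_loose.")
  }
  structure(th, class = "selection_thresholds")
}

#' @export
print.selection_thresholds <- function(x, ...) {
  cat("<selection_thresholds>\n")
  for (nm in setdiff(names(x), "abundance_policy")) {
    cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-16s %s\n", "abundance_policy", x$abundance_policy))
  invisible(x)
}
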