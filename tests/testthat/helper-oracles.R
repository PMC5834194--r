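# Independent oracles and fixture builders. Everything here is written as
# plain straight-line R, deliberately not sharing code paths with the
# package internals it checks.

# Exhaustive two-sided permutation t-test over all group labelings.
perm_ttest_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  tstat <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  }
  obs <- abs(tstat(x, y))
  idx <- utils::combn(length(pooled), nx)
  ts <- apply(idx, 2, function(ii) abs(tstat(pooled[ii], pooled[-ii])))
  mean(ts >= obs - 1e-12)
}

# One-sided hypergeometric tail by direct enumeration with choose().
fisher_tail_bruteforce <- function(a, b, c, d) {
  n1 <- a + b
  K <- a + c
  N <- a + b + c + d
  ks <- max(0, K - (N - n1)):min(K, n1)
  probs <- choose(K, ks) * choose(N - K, n1 - ks) / choose(N, n1)
  sum(probs[ks >= a])
}

# Per-base membership overlap check for half-open intervals.
overlap_bruteforce <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(FALSE)
  any(seq(s1, e1 - 1) %in% seq(s2, e2 - 1))
}

# Exhaustive nearest-coding-gene scan with explicit tie handling.
nearest_bruteforce <- function(l, coding) {
  best <- NULL
  for (i in seq_len(nrow(coding))) {
    g <- coding[i, ]
    if (g$chrom != l$chrom) next
    gap <- if (g$start >= l$end) {
      g$start - l$end
    } else if (l$start >= g$end) {
      l$start - g$end
    } else {
      0
    }
    if (is.null(best) || gap < best$gap ||
        (gap == best$gap && g$start < best$start) ||
        (gap == best$gap && g$start == best$start && g$gene_id < best$gene_id)) {
      best <- list(gene_id = g$gene_id, gap = gap, start = g$start)
    }
  }
  best
}

# Straight-line re-implementation of the complete selection rule set
# (abundance / zero-denominator / concordance / tiered significance),
# written with per-gene loops.
reference_select <- function(datasets, annotation, th) {
  lnc <- if (is.null(annotation)) {
    datasets[[1]]$gene_id
  } else {
    annotation$gene_id[annotation$biotype == "lncRNA"]
  }
  common <- lnc
  for (d in datasets) common <- common[common %in% d$gene_id]
  rows <- list()
  for (g in common) {
    per <- list()
    for (d in datasets) {
      ctrl <- as.numeric(d[d$gene_id == g, attr(d, "control_samples")])
      trt <- as.numeric(d[d$gene_id == g, attr(d, "treated_samples")])
      per[[length(per) + 1]] <- list(
        m = mean(c(ctrl, trt)),
        lfc = log2(mean(trt) / mean(ctrl)),
        p = tryCatch(stats::t.test(trt, ctrl)$p.value,
                     error = function(e) NA_real_),
        bad = mean(ctrl == 0) >= th$zero_fraction,
        dir = attr(d, "treatment_direction")
      )
    }
    m <- sapply(per, `[[`, "m")
    low <- m < th$min_avg_fpkm
    removed <- if (th$abundance_policy == "all") all(low) else any(low)
    if (removed) next
    if (any(sapply(per, `[[`, "bad"))) next
    lfc <- sapply(per, `[[`, "lfc")
    dirs <- sapply(per, `[[`, "dir")
    syn <- all(ifelse(dirs == "toward_synthetic",
                      lfc > th$min_abs_log2fc, lfc < -th$min_abs_log2fc))
    con <- all(ifelse(dirs == "toward_synthetic",
                      lfc < -th$min_abs_log2fc, lfc > th$min_abs_log2fc))
    if (!syn && !con) next
    p <- sapply(per, `[[`, "p")
    sig <- !any(is.na(p)) && sum(p < th$p_strict) >= th$n_strict &&
      all(p < th$p_loose)
    rows[[g]] <- data.frame(
      gene_id = g,
      phenotype_class = if (syn) "synthetic_up" else "contractile_up",
      significant = sig, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), phenotype_class = character(),
                      significant = logical())
  }
  out[order(out$gene_id), , drop = FALSE]
}

# Deterministic near-noiseless dataset with exact group means: each sample
# is the group mean times (1 + small fixed relative offset), so log2
# fold changes equal log2(trt/ctrl) exactly and t-tests are well defined.
handcrafted_dataset <- function(name, direction, ctrl_means, trt_means,
                                rel = c(-0.03, -0.01, 0.01, 0.03)) {
  genes <- names(ctrl_means)
  n <- length(rel)
  tab <- tibble::tibble(gene_id = genes)
  for (j in seq_len(n)) tab[[paste0(name, "_c", j)]] <- unname(ctrl_means) * (1 + rel[j])
  for (j in seq_len(n)) tab[[paste0(name, "_t", j)]] <- unname(trt_means) * (1 + rel[j])
  expression_dataset(tab, name, paste0(name, "_c", seq_len(n)),
                     paste0(name, "_t", seq_len(n)), direction)
}

# Small three-dataset smooth-muscle bundle around a named log2fc matrix:
# `lfc` is genes x 3 with columns (synthetic-inducing, contractile 1,
# contractile 2) giving the exact treated/control log2 ratio per dataset.
handcrafted_smooth <- function(lfc, baseline = 20) {
  stopifnot(ncol(lfc) == 3)
  genes <- rownames(lfc)
  dirs <- c("toward_synthetic", "toward_contractile", "toward_contractile")
  names <- c("syn", "con1", "con2")
  lapply(1:3, function(j) {
    ctrl <- stats::setNames(rep(baseline, length(genes)), genes)
    handcrafted_dataset(names[j], dirs[j], ctrl, ctrl * 2^lfc[, j])
  })
}

# Annotation-free small simulated selection inputs (annotation + expression
# only; skips peaks and miRNA stages for speed).
simulate_selection_inputs <- function(config) {
  ann <- simulate_annotation(config)
  expr <- simulate_expression(config, ann$annotation, ann$truth)
  list(annotation = ann$annotation, datasets = expr$datasets,
       truth = expr$truth)
}

smooth_only <- function(datasets) {
  Filter(function(d) attr(d, "treatment_direction") != "toward_differentiated",
         datasets)
}

skeletal_only <- function(datasets) {
  Filter(function(d) attr(d, "treatment_direction") == "toward_differentiated",
         datasets)[[1]]
}
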