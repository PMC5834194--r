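# Deterministic synthetic-study generator with planted ground truth. It
# emulates the structure of the real study: three smooth-muscle
# differentiation datasets whose treatments push the phenotype in opposing
# directions (one synthetic-inducing, two contractile-inducing), one
# skeletal myoblast-differentiation dataset, ChIP-seq peaks for a few dozen
# transcription factors, a miRcode-style miRNA target track and a miRNA
# fold-ratio table. Every stage of the pipeline has planted true positives
# recorded in a machine-readable truth manifest.

#' Configuration of the synthetic study
#'
#' Defaults describe the emulated study conditions: 300 lncRNAs and 100
#' protein-coding genes on two synthetic chromosomes; one
#' synthetic-inducing plus two contractile-inducing smooth-muscle datasets
#' and one skeletal dataset, 4 samples per group; 15 planted synthetic-up
#' and 10 contractile-up lncRNAs with |log2 fold change| 1; log-normal
#' baselines with multiplicative within-group noise at 10% coefficient of
#' variation; 20% of null lncRNAs below the 5-FPKM abundance floor and 5%
#' zero-inflated in their control groups; 30 transcription factors of which
#' 3 are truly enriched in synthetic-up promoters (hit probabilities
#' 0.9 vs 0.1); 12 miRNA families with 1-4 binding sites per planted pair.
#'
#' @param seed Integer seed; fully determines all generated files.
#' @param n_lncrna,n_coding Gene counts by biotype.
#' @param n_datasets_synthetic,n_datasets_contractile Numbers of
#'   smooth-muscle datasets pushing toward each phenotype.
#' @param include_skeletal Generate the skeletal differentiation dataset.
#' @param samples_per_group Samples per control/treated group.
#' @param n_planted_synthetic_up,n_planted_contractile_up Planted candidate
#'   counts.
#' @param effect_log2fc Planted absolute log2 fold change.
#' @param baseline_fpkm_log_mean,baseline_fpkm_log_sd Log-normal baseline
#'   FPKM parameters (natural-log scale).
#' @param noise_cv Within-group coefficient of variation of the
#'   multiplicative log-normal sample noise.
#' @param frac_low_abundance Fraction of null lncRNAs given baselines below
#'   the abundance floor in all datasets.
#' @param frac_zero_inflated Fraction of null lncRNAs whose control groups
#'   are half zeros (must be caught by the zero-denominator rule).
#' @param n_tfs,enriched_tf_count Transcription-factor counts.
#' @param peak_hit_prob_enriched,peak_hit_prob_background Probability that
#'   a TF peak lands in a synthetic-up promoter (enriched TFs) vs any other
#'   lncRNA promoter.
#' @param n_mirnas Number of miRNA families.
#' @param n_cerna_lncrnas Planted synthetic-up lncRNAs given miRNA binding
#'   sites.
#' @param sites_per_pair_range Inclusive range of binding sites per
#'   (lncRNA, miRNA) pair.
#' @param n_chroms,chrom_length Synthetic genome shape.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_lncrna = 300L,
                              n_coding = 100L,
                              n_datasets_synthetic = 1L,
                              n_datasets_contractile = 2L,
                              include_skeletal = TRUE,
                              samples_per_group = 4L,
                              n_planted_synthetic_up = 15L,
                              n_planted_contractile_up = 10L,
                              effect_log2fc = 1,
                              baseline_fpkm_log_mean = 3,
                              baseline_fpkm_log_sd = 1,
                              noise_cv = 0.1,
                              frac_low_abundance = 0.2,
                              frac_zero_inflated = 0.05,
                              n_tfs = 30L,
                              enriched_tf_count = 3L,
                              peak_hit_prob_enriched = 0.9,
                              peak_hit_prob_background = 0.1,
                              n_mirnas = 12L,
                              n_cerna_lncrnas = 3L,
                              sites_per_pair_range = c(1L, 4L),
                              n_chroms = 2L,
                              chrom_length = 2e7) {
  cfg <- as.list(environment())
  n_planted <- cfg$n_planted_synthetic_up + cfg$n_planted_contractile_up
  if (n_planted > cfg$n_lncrna) {
    rlang::abort("planted counts must not exceed n_lncrna.")
  }
  if (n_planted > cfg$n_coding) {
    rlang::abort("need n_coding >= planted count: each planted lncRNA gets a dedicated neighbor.")
  }
  probs <- c(cfg$peak_hit_prob_enriched, cfg$peak_hit_prob_background,
             cfg$frac_low_abundance, cfg$frac_zero_inflated)
  if (any(probs < 0 | probs > 1)) rlang::abort("probabilities must lie in [0, 1].")
  if (cfg$seed >= 2^31 - 5) rlang::abort("seed too large.")
  structure(cfg, class = "simulation_config")
}

with_stage_seed <- function(config, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(config$seed) + offset)
  code
}

chrom_names <- function(config) paste0("chr", seq_len(config$n_chroms))

#' Generate the synthetic gene annotation
#'
#' Places lncRNA and protein-coding genes on the synthetic chromosomes with
#' random strands and 1-4 exons per gene. Each planted candidate lncRNA is
#' placed with one dedicated protein-coding neighbor at a gap of a few
#' hundred bp, while all other inter-gene gaps exceed 5 kb, so the
#' designated neighbor is the unambiguous nearest coding gene.
#'
#' @param config A [simulation_config()].
#'
#' @return A list: `annotation` (see [read_gtf()]) and `truth`, a list
#'   whose `planted` tibble records each planted lncRNA's class and
#'   designated neighbor.
#' @export
simulate_annotation <- function(config) {
  with_stage_seed(config, 1L, {
    lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncrna))
    cod_ids <- sprintf("PCG%04d", seq_len(config$n_coding))
    n_planted <- config$n_planted_synthetic_up + config$n_planted_contractile_up
    planted <- tibble::tibble(
      gene_id = lnc_ids[seq_len(n_planted)],
      class = rep(c("synthetic_up", "contractile_up"),
                  c(config$n_planted_synthetic_up,
                    config$n_planted_contractile_up)),
      neighbor_gene_id = cod_ids[seq_len(n_planted)]
    )

    # placement units: planted lncRNA + its neighbor travel together
    units <- c(
      lapply(seq_len(n_planted), function(i) {
        c(planted$gene_id[i], planted$neighbor_gene_id[i])
      }),
      as.list(c(setdiff(lnc_ids, planted$gene_id),
                setdiff(cod_ids, planted$neighbor_gene_id)))
    )
    units <- units[sample.int(length(units))]

    gene_len <- function(n) round(stats::runif(n, 1000, 8000))
    n_genes <- sum(lengths(units))
    v_id <- character(n_genes); v_chrom <- character(n_genes)
    v_start <- numeric(n_genes); v_end <- numeric(n_genes)
    v_strand <- character(n_genes)
    chroms <- chrom_names(config)
    chrom_i <- 1L
    cursor <- 5000
    row_i <- 0L
    for (u in units) {
      lens <- gene_len(length(u))
      pair_gap <- if (length(u) == 2) round(stats::runif(1, 200, 800)) else 0
      unit_len <- sum(lens) + pair_gap
      if (cursor + unit_len > config$chrom_length - 5000) {
        chrom_i <- chrom_i + 1L
        if (chrom_i > length(chroms)) {
          rlang::abort("cannot place all genes; increase chrom_length or n_chroms.")
        }
        cursor <- 5000
      }
      pos <- cursor
      for (k in seq_along(u)) {
        row_i <- row_i + 1L
        v_id[row_i] <- u[k]
        v_chrom[row_i] <- chroms[chrom_i]
        v_start[row_i] <- pos
        v_end[row_i] <- pos + lens[k]
        v_strand[row_i] <- sample(c("+", "-"), 1)
        pos <- pos + lens[k] + pair_gap
      }
      cursor <- cursor + unit_len + round(stats::runif(1, 6000, 20000))
    }
    placed <- tibble::tibble(gene_id = v_id, chrom = v_chrom,
                             start = v_start, end = v_end, strand = v_strand)

    make_exons <- function(start, end) {
      k <- sample.int(4L, 1)
      if (k == 1L) {
        return(tibble::tibble(start = start, end = end))
      }
      len <- end - start
      cuts <- sort(sample.int(len - 1L, 2L * (k - 1L))) + start
      starts <- c(start, cuts[seq(2, length(cuts), by = 2)])
      ends <- c(cuts[seq(1, length(cuts), by = 2)], end)
      tibble::tibble(start = starts, end = ends)
    }
    placed$exons <- lapply(seq_len(nrow(placed)), function(i) {
      make_exons(placed$start[i], placed$end[i])
    })
    placed$biotype <- ifelse(placed$gene_id %in% lnc_ids, "lncRNA",
                             "protein_coding")
    placed$gene_name <- tolower(placed$gene_id)
    placed$tss <- ifelse(placed$strand == "-", placed$end - 1, placed$start)
    annotation <- new_annotation(
      placed[, c("gene_id", "gene_name", "biotype", "chrom", "start", "end",
                 "strand", "tss", "exons")],
      genome_build = "synthetic"
    )
    list(annotation = annotation, truth = list(planted = planted))
  })
}

#' Generate the synthetic expression datasets
#'
#' Baseline FPKM is log-normal per gene and shared across datasets;
#' per-sample values get multiplicative log-normal noise with coefficient
#' of variation `noise_cv`. Planted synthetic-up lncRNAs gain
#' `+effect_log2fc` in treated groups of synthetic-inducing datasets and
#' `-effect_log2fc` in contractile-inducing ones (mirror for
#' contractile-up); their designated neighbor genes share the same effect,
#' creating the high fold-change correlation of the cis-acting hypothesis.
#' In the skeletal dataset each planted gene is randomly assigned a
#' same-direction, opposite-direction or low-expression behaviour,
#' recorded in the truth. A fraction of null lncRNAs are low-abundance
#' (below the FPKM floor everywhere) and a further fraction are
#' zero-inflated: half of every control group is set to exactly 0 so the
#' zero-denominator rule must fire.
#'
#' @param config A [simulation_config()].
#' @param annotation,truth Output of [simulate_annotation()].
#'
#' @return A list: `datasets` (named list of [expression_dataset()]) and
#'   the augmented `truth` (adds `skeletal_direction` to `planted`, plus
#'   `low_abundance` and `zero_inflated` id vectors).
#' @export
simulate_expression <- function(config, annotation, truth) {
  with_stage_seed(config, 2L, {
    genes <- annotation$gene_id
    n <- length(genes)
    planted <- truth$planted
    special <- c(planted$gene_id, planted$neighbor_gene_id)

    sdlog <- sqrt(log(1 + config$noise_cv^2))
    baseline <- stats::rlnorm(n, config$baseline_fpkm_log_mean,
                              config$baseline_fpkm_log_sd)
    names(baseline) <- genes
    # planted genes and their neighbors must clear the abundance floor
    floor_b <- 4 * 5
    if (length(special) > 0) {
      low_b <- baseline[special] < floor_b
      baseline[special][low_b] <- floor_b + stats::rlnorm(sum(low_b), 2, 0.5)
    }

    null_lnc <- setdiff(genes[startsWith(genes, "LNC")], planted$gene_id)
    low_abundance <- sample(null_lnc,
                            round(config$frac_low_abundance * length(null_lnc)))
    baseline[low_abundance] <- stats::runif(length(low_abundance), 0.2, 4)
    zero_inflated <- sample(setdiff(null_lnc, low_abundance),
                            round(config$frac_zero_inflated * length(null_lnc)))

    planted$skeletal_direction <- sample(
      c("same", "opposite", "low"), nrow(planted), replace = TRUE,
      prob = c(0.55, 0.3, 0.15)
    )

    # signed planted effect on the *treated* group, per direction pushed
    effect_for <- function(direction) {
      eff <- stats::setNames(rep(0, n), genes)
      # oriented change toward the phenotype the treatment induces
      sgn_syn <- ifelse(planted$class == "synthetic_up", +1, -1)
      per_gene <- switch(direction,
        toward_synthetic = sgn_syn,
        toward_contractile = -sgn_syn,
        toward_differentiated = ifelse(planted$skeletal_direction == "same",
                                       -sgn_syn,
                                       ifelse(planted$skeletal_direction == "opposite",
                                              sgn_syn, 0))
      )
      eff[planted$gene_id] <- per_gene * config$effect_log2fc
      eff[planted$neighbor_gene_id] <- per_gene * config$effect_log2fc
      eff
    }

    specs <- list(
      list(name = "smooth_synthetic", direction = "toward_synthetic"),
      if (config$n_datasets_contractile >= 1) {
        lapply(seq_len(config$n_datasets_contractile), function(i) {
          list(name = paste0("smooth_contractile_", i),
               direction = "toward_contractile")
        })
      }
    )
    specs <- c(list(specs[[1]]), specs[[2]])
    if (config$n_datasets_synthetic > 1) {
      specs <- c(specs, lapply(seq_len(config$n_datasets_synthetic - 1),
                               function(i) {
        list(name = paste0("smooth_synthetic_", i + 1),
             direction = "toward_synthetic")
      }))
    }
    if (config$include_skeletal) {
      specs <- c(specs, list(list(name = "skeletal",
                                  direction = "toward_differentiated")))
    }

    m <- config$samples_per_group
    datasets <- lapply(specs, function(sp) {
      eff <- effect_for(sp$direction)
      base_ds <- baseline
      if (sp$direction == "toward_differentiated") {
        low_sk <- planted$gene_id[planted$skeletal_direction == "low"]
        base_ds[low_sk] <- stats::runif(length(low_sk), 0.2, 4)
      }
      noise <- function() {
        matrix(stats::rlnorm(n * m, -sdlog^2 / 2, sdlog), n, m)
      }
      ctrl <- base_ds * noise()
      trt <- (base_ds * 2^eff) * noise()
      zi <- genes %in% zero_inflated
      if (any(zi)) {
        k <- ceiling(m / 2)
        for (i in which(zi)) {
          ctrl[i, sample.int(m, k)] <- 0
        }
      }
      tab <- tibble::as_tibble(cbind(ctrl, trt), .name_repair = "minimal")
      names(tab) <- c(paste0(sp$name, "_ctrl_", seq_len(m)),
                      paste0(sp$name, "_trt_", seq_len(m)))
      tab <- dplyr::bind_cols(tibble::tibble(gene_id = genes), tab)
      expression_dataset(tab, sp$name,
                         control_samples = paste0(sp$name, "_ctrl_", seq_len(m)),
                         treated_samples = paste0(sp$name, "_trt_", seq_len(m)),
                         treatment_direction = sp$direction)
    })
    names(datasets) <- vapply(specs, `[[`, character(1), "name")

    truth$planted <- planted
    truth$low_abundance <- low_abundance
    truth$zero_inflated <- zero_inflated
    list(datasets = datasets, truth = truth)
  })
}

#' Generate ChIP-seq peaks for the synthetic transcription factors
#'
#' Truly enriched TFs drop a peak inside each planted synthetic-up
#' promoter with probability `peak_hit_prob_enriched` and inside every
#' other lncRNA promoter at the background rate; background TFs use the
#' background rate everywhere. Each TF additionally gets a handful of
#' random genome-wide peaks. Peaks never exceed chromosome bounds.
#'
#' @param config A [simulation_config()].
#' @param annotation,truth Output of the upstream generators.
#'
#' @return A list: `peaks` (tibble `chrom`, `start`, `end`, `tf_name`) and
#'   the augmented `truth` (adds `enriched_tfs`).
#' @export
simulate_peaks <- function(config, annotation, truth) {
  with_stage_seed(config, 3L, {
    tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
    enriched <- tfs[seq_len(config$enriched_tf_count)]
    lnc <- filter_biotype(annotation, "lncRNA")
    lens <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                            chrom_names(config))
    prom <- promoter_windows(lnc, chrom_lengths = lens)
    syn_up <- truth$planted$gene_id[truth$planted$class == "synthetic_up"]

    rows <- list()
    for (tf in tfs) {
      p_hit <- ifelse(prom$gene_id %in% syn_up & tf %in% enriched,
                      config$peak_hit_prob_enriched,
                      config$peak_hit_prob_background)
      hits <- which(stats::runif(nrow(prom)) < p_hit)
      if (length(hits) > 0) {
        w <- round(stats::runif(length(hits), 150, 400))
        center <- round(stats::runif(length(hits), prom$start[hits],
                                     prom$end[hits] - 1))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chrom = prom$chrom[hits],
          start = pmax(0, center - w %/% 2),
          end = pmin(config$chrom_length, center + w %/% 2 + 1),
          tf_name = tf
        )
      }
      s <- round(stats::runif(20, 0, config$chrom_length - 500))
      rows[[length(rows) + 1L]] <- tibble::tibble(   # genome-wide background
        chrom = sample(chrom_names(config), 20, replace = TRUE),
        start = s, end = s + round(stats::runif(20, 150, 400)),
        tf_name = tf
      )
    }
    peaks <- dplyr::arrange(dplyr::bind_rows(rows), .data$tf_name,
                            .data$chrom, .data$start)
    truth$enriched_tfs <- enriched
    list(peaks = peaks, truth = truth)
  })
}

#' Generate the miRNA target track and fold-ratio table
#'
#' A subset of the planted synthetic-up lncRNAs (which decrease upon
#' differentiation) become ceRNA candidates. Truly inverse miRNAs get
#' binding sites inside those lncRNAs' exons and fold ratios above 1 at
#' both time points; decoy miRNAs also get sites but ratios straddling 1,
#' so the inverse-expression filter must exclude them. Remaining miRNAs
#' receive sites in non-candidate lncRNAs with random ratios.
#'
#' @param config A [simulation_config()].
#' @param annotation,truth Output of the upstream generators.
#'
#' @return A list: `mirna_track` (tibble `chrom`, `start`, `end`,
#'   `mirna_id`), `mirna_fc` (tibble `mirna_id`, `ratio_t1`, `ratio_t2`)
#'   and the augmented `truth` (adds the `cerna` pair tibble with
#'   `truly_inverse` flags and `cerna_lncrnas`).
#' @export
simulate_mirna_data <- function(config, annotation, truth) {
  with_stage_seed(config, 4L, {
    syn_up <- truth$planted$gene_id[truth$planted$class == "synthetic_up"]
    cerna_lncs <- utils::head(syn_up, config$n_cerna_lncrnas)
    mirnas <- sprintf("miR-s%02d", seq_len(config$n_mirnas))
    n_inv <- max(2L, config$n_mirnas %/% 3)
    n_dec <- max(2L, config$n_mirnas %/% 3)
    inv_pool <- mirnas[seq_len(n_inv)]
    dec_pool <- mirnas[n_inv + seq_len(n_dec)]
    other_pool <- setdiff(mirnas, c(inv_pool, dec_pool))

    site_in_exon <- function(gene, mir) {
      g <- annotation[annotation$gene_id == gene, ]
      ex <- g$exons[[1]]
      ex <- ex[ex$end - ex$start >= 30, , drop = FALSE]
      if (nrow(ex) == 0) ex <- g$exons[[1]]
      j <- sample.int(nrow(ex), 1)
      s <- round(stats::runif(1, ex$start[j], ex$end[j] - 20))
      tibble::tibble(chrom = g$chrom, start = s, end = s + 15, mirna_id = mir)
    }

    sites <- list()
    pairs <- list()
    rng <- config$sites_per_pair_range
    for (lnc in cerna_lncs) {
      inv <- sample(inv_pool, sample(2:min(3, length(inv_pool)), 1))
      dec <- sample(dec_pool, min(2, length(dec_pool)))
      for (mir in c(inv, dec)) {
        k <- sample(seq(rng[1], rng[2]), 1)
        for (s in seq_len(k)) {
          sites[[length(sites) + 1L]] <- site_in_exon(lnc, mir)
        }
        pairs[[length(pairs) + 1L]] <- tibble::tibble(
          lncrna_id = lnc, mirna_id = mir, n_sites = k,
          truly_inverse = mir %in% inv_pool
        )
      }
    }
    # a little background: other miRNAs hit non-candidate lncRNAs
    null_lnc <- setdiff(filter_biotype(annotation, "lncRNA")$gene_id,
                        truth$planted$gene_id)
    for (mir in other_pool) {
      for (lnc in sample(null_lnc, 2)) {
        sites[[length(sites) + 1L]] <- site_in_exon(lnc, mir)
      }
    }
    track <- dplyr::arrange(dplyr::bind_rows(sites), .data$chrom,
                            .data$start, .data$mirna_id)

    ratio <- function(lo, hi) round(stats::runif(length(mirnas), lo, hi), 3)
    mirna_fc <- tibble::tibble(
      mirna_id = mirnas,
      ratio_t1 = ifelse(mirnas %in% inv_pool, ratio(1.3, 3),
                        ifelse(mirnas %in% dec_pool, ratio(1.2, 2.5),
                               ratio(0.5, 1.5))),
      ratio_t2 = ifelse(mirnas %in% inv_pool, ratio(1.3, 3),
                        ifelse(mirnas %in% dec_pool, ratio(0.3, 0.9),
                               ratio(0.5, 1.5)))
    )
    truth$cerna <- dplyr::bind_rows(pairs)
    truth$cerna_lncrnas <- cerna_lncs
    list(mirna_track = track, mirna_fc = mirna_fc, truth = truth)
  })
}

#' Simulate a complete study with planted ground truth
#'
#' Runs all generators in order and bundles their outputs.
#'
#' @param config A [simulation_config()].
#'
#' @return A list of class `lnc_study` with `annotation`, `datasets`,
#'   `peaks`, `mirna_track`, `mirna_fc`, `truth` and the `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  ann <- simulate_annotation(config)
  expr <- simulate_expression(config, ann$annotation, ann$truth)
  pk <- simulate_peaks(config, ann$annotation, expr$truth)
  mir <- simulate_mirna_data(config, ann$annotation, pk$truth)
  structure(
    list(annotation = ann$annotation, datasets = expr$datasets,
         peaks = pk$peaks, mirna_track = mir$mirna_track,
         mirna_fc = mir$mirna_fc, truth = mir$truth, config = config),
    class = "lnc_study"
  )
}

#' Write a simulated study to disk
#'
#' Emits exactly the formats the pipeline consumes: `annotation.gtf`, one
#' `expr_<name>.tsv` per dataset, `peaks.bed` (TF in the name column),
#' `mirna_sites.bed` (miRNA in the name column), `mirna_fold_ratios.tsv`,
#' a `manifest.yaml` tying them together, and `ground_truth.json`.
#' Identical configurations produce byte-identical files.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if missing).
#'
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(study$annotation, file.path(dir, "annotation.gtf"))
  ds_entries <- lapply(study$datasets, function(d) {
    fn <- paste0("expr_", dataset_name(d), ".tsv")
    write_expression_table(d, file.path(dir, fn))
    list(name = dataset_name(d), path = fn,
         control_samples = attr(d, "control_samples"),
         treated_samples = attr(d, "treated_samples"),
         treatment_direction = dataset_direction(d))
  })
  write_bed(dplyr::rename(study$peaks, name = "tf_name"),
            file.path(dir, "peaks.bed"))
  write_bed(dplyr::rename(study$mirna_track, name = "mirna_id"),
            file.path(dir, "mirna_sites.bed"))
  readr::write_tsv(study$mirna_fc, file.path(dir, "mirna_fold_ratios.tsv"))
  manifest <- list(
    annotation = "annotation.gtf",
    datasets = unname(ds_entries),
    peaks = "peaks.bed",
    mirna_track = "mirna_sites.bed",
    mirna_fold_ratios = "mirna_fold_ratios.tsv"
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  truth <- study$truth
  truth$planted <- as.list(truth$planted)
  truth$cerna <- as.list(truth$cerna)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.yaml"))
}

#' Score a candidate table against the planted truth
#'
#' Sensitivity counts planted lncRNAs recovered in their planted class with
#' the significance label; false positives are significant concordant rows
#' whose gene was not planted.
#'
#' @param candidates A table from [select_candidates()].
#' @param truth The `truth` element of a simulated study.
#'
#' @return A one-row tibble: `n_planted`, `n_recovered`, `sensitivity`,
#'   `false_positives`.
#' @export
score_selection <- function(candidates, truth) {
  planted <- truth$planted
  hits <- dplyr::inner_join(
    tibble::as_tibble(candidates)[, c("gene_id", "phenotype_class", "significant")],
    planted[, c("gene_id", "class")], by = "gene_id"
  )
  n_rec <- sum(hits$phenotype_class == hits$class & hits$significant)
  fp <- sum(candidates$significant & !candidates$gene_id %in% planted$gene_id)
  tibble::tibble(
    n_planted = nrow(planted), n_recovered = n_rec,
    sensitivity = n_rec / nrow(planted), false_positives = fp
  )
}
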