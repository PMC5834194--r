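small_cfg <- function(seed = 7, ...) {
  simulation_config(seed = seed, n_lncrna = 40, n_coding = 20,
                    n_planted_synthetic_up = 4, n_planted_contractile_up = 3,
                    n_tfs = 8, enriched_tf_count = 2, n_mirnas = 9,
                    n_cerna_lncrnas = 2, ...)
}

test_that("the generator is fully deterministic under its seed", {
  s1 <- simulate_study(small_cfg())
  s2 <- simulate_study(small_cfg())
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(lapply(s1$datasets, tibble::as_tibble),
                   lapply(s2$datasets, tibble::as_tibble))
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$mirna_track, s2$mirna_track)
  expect_identical(s1$truth, s2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(s1, d1)
  write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }

  s3 <- simulate_study(small_cfg(seed = 8))
  expect_false(identical(s1$annotation$start, s3$annotation$start))
})

test_that("generated annotation is internally consistent with recoverable neighbors", {
  sim <- simulate_annotation(small_cfg())
  ann <- sim$annotation
  for (i in seq_len(nrow(ann))) {
    ex <- ann$exons[[i]]
    expect_true(all(ex$start >= ann$start[i] & ex$end <= ann$end[i]))
    expect_true(all(ex$start < ex$end))
    expect_true(all(diff(ex$start) > 0))
  }
  expect_true(all(ann$tss == ifelse(ann$strand == "-", ann$end - 1, ann$start)))

  planted <- sim$truth$planted
  got <- nearest_gene(ann[match(planted$gene_id, ann$gene_id), ],
                      filter_biotype(ann, "protein_coding"))
  expect_equal(got$neighbor_gene_id, planted$neighbor_gene_id)
})

test_that("planted effects, zero inflation and null calm are realised in expression", {
  cfg <- small_cfg(seed = 11)
  inp <- simulate_selection_inputs(cfg)
  syn_ds <- inp$datasets$smooth_synthetic
  fc <- fold_change_table(syn_ds)
  planted <- inp$truth$planted

  # planted synthetic-up genes sit near +effect in the synthetic-inducing set;
  # with samples_per_group 4 and cv 0.1 three standard errors are ~0.22
  syn_up <- planted$gene_id[planted$class == "synthetic_up"]
  expect_true(all(abs(fc$log2fc[match(syn_up, fc$gene_id)] -
                        cfg$effect_log2fc) < 0.25))
  con_up <- planted$gene_id[planted$class == "contractile_up"]
  expect_true(all(abs(fc$log2fc[match(con_up, fc$gene_id)] +
                        cfg$effect_log2fc) < 0.25))

  # zero-inflated genes trip the zero-denominator rule in every smooth dataset
  for (g in inp$truth$zero_inflated) {
    expect_true(zero_denominator_check(syn_ds, g))
  }

  # low-abundance genes stay under the floor in all datasets
  for (d in smooth_only(inp$datasets)) {
    m <- as.matrix(d[match(inp$truth$low_abundance, d$gene_id), -1])
    expect_true(all(rowMeans(m) < 5))
  }

  # unplanted genes rarely exceed the fold-change cutoff
  null_ids <- setdiff(inp$annotation$gene_id[inp$annotation$biotype == "lncRNA"],
                      c(planted$gene_id, inp$truth$zero_inflated))
  null_fc <- fc$log2fc[match(null_ids, fc$gene_id)]
  expect_gt(mean(abs(null_fc) < 0.5), 0.95)
})

test_that("peaks stay inside chromosome bounds and track counts match the truth", {
  study <- simulate_study(small_cfg(seed = 13))
  expect_true(all(study$peaks$start >= 0))
  expect_true(all(study$peaks$end <= study$config$chrom_length))
  expect_true(all(study$peaks$start < study$peaks$end))

  truth_pairs <- study$truth$cerna
  counted <- count_binding_sites(
    study$annotation[match(unique(truth_pairs$lncrna_id),
                           study$annotation$gene_id), ],
    study$mirna_track
  )
  joined <- dplyr::inner_join(truth_pairs, counted,
                              by = c("lncrna_id", "mirna_id"))
  expect_equal(nrow(joined), nrow(truth_pairs))
  expect_equal(joined$n_binding_sites, joined$n_sites)
})

test_that("a written study loads back to the same analysis inputs", {
  study <- simulate_study(small_cfg(seed = 17))
  dir <- withr::local_tempdir()
  manifest <- write_study(study, dir)
  loaded <- load_study(manifest)

  expect_equal(loaded$annotation$start, study$annotation$start)
  expect_equal(loaded$annotation$exons, study$annotation$exons)
  expect_equal(names(loaded$datasets), names(study$datasets))
  for (nm in names(study$datasets)) {
    expect_equal(tibble::as_tibble(loaded$datasets[[nm]]),
                 tibble::as_tibble(study$datasets[[nm]]),
                 tolerance = 1e-12)
    expect_equal(attr(loaded$datasets[[nm]], "treatment_direction"),
                 attr(study$datasets[[nm]], "treatment_direction"))
  }
  expect_equal(nrow(loaded$peaks), nrow(study$peaks))
  expect_equal(loaded$mirna_fc, study$mirna_fc)

  cand_mem <- select_candidates(smooth_only(study$datasets), study$annotation)
  cand_disk <- select_candidates(smooth_only(loaded$datasets), loaded$annotation)
  expect_equal(tibble::as_tibble(cand_disk), tibble::as_tibble(cand_mem),
               tolerance = 1e-12)
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_lncrna = 5, n_planted_synthetic_up = 10),
               "planted")
  expect_error(simulation_config(peak_hit_prob_enriched = 1.5), "0, 1")
  expect_error(
    simulate_study(simulation_config(n_lncrna = 400, n_coding = 400,
                                     chrom_length = 1e5, n_chroms = 1)),
    "chrom_length"
  )
})
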