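test_that("the abundance filter removes genes only when low under the chosen policy", {
  mk <- function(name, means) {
    handcrafted_dataset(name, "toward_synthetic", means, means)
  }
  genes <- c(keep = 6, border = 5, low = 1)
  d1 <- mk("d1", c(keep = 6.0, border = 5.0, low = 1.0))
  d2 <- mk("d2", c(keep = 2.0, border = 1.0, low = 1.0))
  d3 <- mk("d3", c(keep = 1.0, border = 1.0, low = 1.0))

  kept <- abundance_filter(list(d1, d2, d3))
  # high in one dataset suffices under the default "all" policy
  expect_true("keep" %in% kept$gene_id)
  # mean exactly 5 is retained: "lower than 5" is strict
  expect_true("border" %in% kept$gene_id)
  expect_false("low" %in% kept$gene_id)

  kept_any <- abundance_filter(list(d1, d2, d3),
                               selection_thresholds(abundance_policy = "any"))
  expect_false("keep" %in% kept_any$gene_id)
})

test_that("directional concordance requires strict opposing fold changes", {
  mk_records <- function(lfc) {
    tibble::tibble(
      gene_id = "g",
      dataset = c("pdgf", "myocd", "tgfb"),
      treatment_direction = c("toward_synthetic", "toward_contractile",
                              "toward_contractile"),
      log2fc = lfc,
      denominator_valid = TRUE
    )
  }
  cls <- function(lfc) direction_concordance(mk_records(lfc))$phenotype_class
  expect_equal(cls(c(+0.6, -0.6, -0.6)), "synthetic_up")
  expect_equal(cls(c(-0.6, +0.6, +0.6)), "contractile_up")
  expect_equal(cls(c(+0.6, +0.6, -0.6)), "none")   # one dataset violates
  expect_equal(cls(c(+0.5, -0.6, -0.6)), "none")   # 0.5 is not > 0.5

  bad <- mk_records(c(+0.6, -0.6, -0.6))
  bad$denominator_valid[2] <- FALSE
  res <- direction_concordance(bad)
  expect_equal(res$phenotype_class, "none")
  expect_equal(res$reason, "zero_denominator")

  expect_error(
    direction_concordance(mk_records(c(1, -1, -1))[-2, ], n_datasets = 3),
    "per dataset"
  )
})

test_that("the tiered significance rule follows its truth table", {
  expect_true(significance_aggregate(c(0.05, 0.08, 0.20)))
  expect_false(significance_aggregate(c(0.05, 0.08, 0.35)))  # loose bound fails
  expect_false(significance_aggregate(c(0.05, 0.20, 0.25)))  # only 1 strict pass
  expect_false(significance_aggregate(c(0.05, NA, 0.01)))    # undefined p fails
  expect_true(significance_aggregate(
    c(0.15, 0.15, 0.15),
    selection_thresholds(p_strict = 0.2, n_strict = 3, p_loose = 0.2)
  ))
})

test_that("select_candidates recovers exactly the planted genes on a small fixture", {
  cfg <- simulation_config(seed = 101, n_lncrna = 50, n_coding = 20,
                           n_planted_synthetic_up = 3,
                           n_planted_contractile_up = 0,
                           frac_low_abundance = 0.1, frac_zero_inflated = 0.05)
  inp <- simulate_selection_inputs(cfg)
  cand <- select_candidates(smooth_only(inp$datasets), inp$annotation)
  syn <- cand$gene_id[cand$phenotype_class == "synthetic_up"]
  expect_setequal(syn, inp$truth$planted$gene_id)
  expect_true(all(cand$significant[cand$phenotype_class == "synthetic_up"]))
  # lncRNA universe only: no coding gene can appear
  expect_false(any(startsWith(cand$gene_id, "PCG")))
})

test_that("an all-noise fixture yields an empty candidate table", {
  cfg <- simulation_config(seed = 102, n_lncrna = 60, n_coding = 10,
                           n_planted_synthetic_up = 0,
                           n_planted_contractile_up = 0)
  inp <- simulate_selection_inputs(cfg)
  cand <- select_candidates(smooth_only(inp$datasets), inp$annotation)
  expect_equal(nrow(cand), 0)
})

test_that("a gene with half-zero controls in one dataset is excluded by the zero rule", {
  lfc <- matrix(c(1, -1, -1), 1, dimnames = list("g1", NULL))
  ds <- handcrafted_smooth(lfc)
  # corrupt the control group of the synthetic-inducing dataset: 2/4 zeros
  ds[[1]][ds[[1]]$gene_id == "g1", c("syn_c1", "syn_c2")] <- 0
  cand <- select_candidates(ds, annotation = NULL)
  expect_false("g1" %in% cand$gene_id)
})

test_that("selection is monotone in its thresholds", {
  cfg <- simulation_config(seed = 103, n_lncrna = 80, n_coding = 30,
                           n_planted_synthetic_up = 5,
                           n_planted_contractile_up = 5,
                           effect_log2fc = 0.8, noise_cv = 0.2)
  inp <- simulate_selection_inputs(cfg)
  sm <- smooth_only(inp$datasets)
  loose <- select_candidates(sm, inp$annotation,
                             selection_thresholds(min_abs_log2fc = 0.5))
  tight <- select_candidates(sm, inp$annotation,
                             selection_thresholds(min_abs_log2fc = 0.8))
  expect_true(all(tight$gene_id %in% loose$gene_id))

  strict_p <- select_candidates(sm, inp$annotation,
                                selection_thresholds(p_strict = 0.01))
  sig_strict <- strict_p$gene_id[strict_p$significant]
  sig_loose <- loose$gene_id[loose$significant]
  expect_true(all(sig_strict %in% sig_loose))
})

test_that("candidates are sorted by descending mean |log2fc| within each class", {
  cfg <- simulation_config(seed = 104, n_lncrna = 60, n_coding = 30,
                           n_planted_synthetic_up = 5,
                           n_planted_contractile_up = 4)
  inp <- simulate_selection_inputs(cfg)
  cand <- select_candidates(smooth_only(inp$datasets), inp$annotation)
  for (cl in unique(cand$phenotype_class)) {
    m <- cand$mean_abs_log2fc[cand$phenotype_class == cl]
    expect_true(all(diff(m) <= 1e-12))
  }
})

test_that("cross-tissue comparison classifies by sign and screens reliability", {
  lfc <- matrix(
    c(-1.2, 1.2, 1.2,    # gA: contractile_up, smooth oriented +1.2
      -1.2, 1.2, 1.2,    # gB: same but skeletal decreases
      -1.2, 1.2, 1.2,    # gC: skeletal change too small
      -1.2, 1.2, 1.2),   # gD: absent from skeletal data
    4, 3, byrow = TRUE, dimnames = list(paste0("g", LETTERS[1:4]), NULL)
  )
  smooth <- handcrafted_smooth(lfc)
  cand <- select_candidates(smooth, annotation = NULL)
  expect_setequal(cand$gene_id, rownames(lfc))

  sk_genes <- c(gA = 20, gB = 20, gC = 20)
  skeletal <- handcrafted_dataset("sk", "toward_differentiated", sk_genes,
                                  sk_genes * 2^c(0.8, -0.8, 0.3))
  cmp <- cross_tissue_compare(cand, skeletal)
  dir <- stats::setNames(cmp$direction, cmp$gene_id)
  expect_equal(unname(dir["gA"]), "same_direction")
  expect_equal(unname(dir["gB"]), "opposite_direction")
  expect_equal(unname(dir["gC"]), "not_comparable")  # |0.3| below threshold
  expect_equal(unname(dir["gD"]), "not_comparable")  # absent gene
  expect_equal(cmp$smooth_log2fc, rep(1.2, 4), tolerance = 1e-9)

  # a low-abundance skeletal gene is screened out even with a large change
  sk_low <- handcrafted_dataset("sk", "toward_differentiated",
                                c(gA = 2), c(gA = 2 * 2^0.8))
  cmp_low <- cross_tissue_compare(cand, sk_low)
  expect_equal(cmp_low$direction[cmp_low$gene_id == "gA"], "not_comparable")
})
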