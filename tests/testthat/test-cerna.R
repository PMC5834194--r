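two_exon_lnc <- function() {
  tibble::tibble(
    gene_id = "L1", gene_name = "l1", biotype = "lncRNA", chrom = "chr1",
    start = 1000, end = 3000, strand = "+", tss = 1000,
    exons = list(tibble::tibble(start = c(1000, 2500), end = c(1500, 3000)))
  )
}

test_that("binding sites are counted per miRNA over exonic overlap only", {
  lnc <- two_exon_lnc()
  track <- tibble::tibble(
    chrom = "chr1",
    start = c(1100, 1300, 1800, 1490, 2400, 5000),
    end = c(1120, 1320, 1820, 1520, 2520, 5020),
    mirna_id = c("miR-X", "miR-X", "miR-X", "miR-Y", "miR-Y", "miR-Z")
  )
  counts <- count_binding_sites(lnc, track)
  cx <- counts$n_binding_sites[counts$mirna_id == "miR-X"]
  cy <- counts$n_binding_sites[counts$mirna_id == "miR-Y"]
  expect_equal(cx, 2)                  # fully intronic site excluded
  expect_equal(cy, 2)                  # boundary-bridging sites count once each
  expect_false("miR-Z" %in% counts$mirna_id)

  # span mode counts the intronic site too
  counts_span <- count_binding_sites(lnc, track, mode = "span")
  expect_equal(counts_span$n_binding_sites[counts_span$mirna_id == "miR-X"], 3)

  # additive over disjoint track subsets; invariant to exon order
  c1 <- count_binding_sites(lnc, track[track$start < 1400, ])
  c2 <- count_binding_sites(lnc, track[track$start >= 1400, ])
  merged <- dplyr::bind_rows(c1, c2) |>
    dplyr::count(.data$mirna_id, wt = .data$n_binding_sites,
                 name = "n_binding_sites")
  expect_equal(dplyr::arrange(merged, .data$mirna_id)$n_binding_sites,
               dplyr::arrange(counts[-1], .data$mirna_id)$n_binding_sites)

  lnc_rev <- lnc
  lnc_rev$exons[[1]] <- lnc_rev$exons[[1]][2:1, ]
  expect_equal(count_binding_sites(lnc_rev, track)$n_binding_sites,
               counts$n_binding_sites)
})

test_that("the inverse-expression filter requires consistency at every time point", {
  sites <- tibble::tibble(lncrna_id = "L1",
                          mirna_id = c("up2", "mixed", "down2"),
                          n_binding_sites = c(2L, 1L, 3L))
  fc <- tibble::tibble(mirna_id = c("up2", "mixed", "down2"),
                       ratio_t1 = c(1.5, 0.8, 0.5),
                       ratio_t2 = c(2.0, 1.2, 0.7))

  down <- inverse_expression_filter(sites, "down_on_differentiation", fc)
  expect_equal(down$mirna_id, "up2")     # increased at all time points
  expect_true(all(down$passes_inverse_filter))

  up <- inverse_expression_filter(sites, "up_on_differentiation", fc)
  expect_equal(up$mirna_id, "down2")     # mirror rule

  any_mode <- inverse_expression_filter(sites, "down_on_differentiation", fc,
                                        mode = "any")
  expect_setequal(any_mode$mirna_id, c("up2", "mixed"))
})

test_that("the up-filter on reciprocal ratios equals the down-filter (mirror symmetry)", {
  set.seed(53)
  sites <- tibble::tibble(lncrna_id = "L1", mirna_id = paste0("m", 1:20),
                          n_binding_sites = 1L)
  fc <- tibble::tibble(mirna_id = paste0("m", 1:20),
                       ratio_t1 = round(runif(20, 0.3, 3), 3),
                       ratio_t2 = round(runif(20, 0.3, 3), 3))
  fc_recip <- dplyr::mutate(fc, ratio_t1 = 1 / .data$ratio_t1,
                            ratio_t2 = 1 / .data$ratio_t2)
  down <- inverse_expression_filter(sites, "down_on_differentiation", fc)
  up_recip <- inverse_expression_filter(sites, "up_on_differentiation", fc_recip)
  expect_setequal(down$mirna_id, up_recip$mirna_id)
})

test_that("miRNAs absent from the fold-ratio table are dropped with a warning", {
  sites <- tibble::tibble(lncrna_id = "L1", mirna_id = c("known", "unknown"),
                          n_binding_sites = 1L)
  fc <- tibble::tibble(mirna_id = "known", ratio_t1 = 2, ratio_t2 = 3)
  expect_warning(
    res <- inverse_expression_filter(sites, "down_on_differentiation", fc),
    "unknown"
  )
  expect_equal(res$mirna_id, "known")
})

test_that("cerna_candidates composes site counting and the inverse filter", {
  lnc <- two_exon_lnc()
  track <- tibble::tibble(chrom = "chr1", start = c(1100, 1200, 2600),
                          end = c(1120, 1220, 2620),
                          mirna_id = c("inv", "inv", "dec"))
  fc <- tibble::tibble(mirna_id = c("inv", "dec"),
                       ratio_t1 = c(1.8, 1.4), ratio_t2 = c(1.6, 0.6))
  res <- cerna_candidates(lnc, track, "down_on_differentiation", fc)
  expect_equal(res$mirna_id, "inv")
  expect_equal(res$n_binding_sites, 2L)
})
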