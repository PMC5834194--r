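test_that("promoter windows follow the -2000..+500 geometry on both strands", {
  g <- tibble::tibble(gene_id = c("p", "m"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(10000, 10000))
  w <- promoter_windows(g)
  expect_equal(w$start[w$gene_id == "p"], 8000)
  expect_equal(w$end[w$gene_id == "p"], 10500)
  expect_equal(w$start[w$gene_id == "m"], 9501)   # mirror about the 5' base
  expect_equal(w$end[w$gene_id == "m"], 12001)

  # clipping at the chromosome edge
  edge <- tibble::tibble(gene_id = "e", chrom = "chr1", strand = "+", tss = 1000)
  we <- promoter_windows(edge)
  expect_equal(c(we$start, we$end), c(0, 1500))
  expect_true(we$clipped)

  near_end <- tibble::tibble(gene_id = "n", chrom = "chr1", strand = "-",
                             tss = 99900)
  wn <- promoter_windows(near_end, chrom_lengths = c(chr1 = 100000))
  expect_equal(wn$end, 100000)
  expect_true(wn$clipped)

  un <- tibble::tibble(gene_id = "u", chrom = "chr1", strand = "*", tss = 500)
  expect_error(promoter_windows(un), "unstranded")
})

test_that("promoter windows have length 2500, contain the TSS and mirror under genome reflection", {
  set.seed(19)
  L <- 1e6
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:300),
    chrom = "chr1",
    strand = sample(c("+", "-"), 300, replace = TRUE),
    tss = sample(5000:(L - 5000), 300)
  )
  w <- promoter_windows(genes)
  expect_true(all(w$end - w$start == 2500))
  expect_true(all(w$start <= genes$tss & genes$tss < w$end))

  mirrored <- genes
  mirrored$tss <- L - 1 - genes$tss
  mirrored$strand <- ifelse(genes$strand == "+", "-", "+")
  wm <- promoter_windows(mirrored)
  # x -> L - x maps [s, e) onto [L - e, L - s)
  expect_equal(wm$start, L - w$end)
  expect_equal(wm$end, L - w$start)
})

test_that("peak incidence is a >=1 bp half-open overlap, once per (gene, TF)", {
  prom <- promoter_windows(tibble::tibble(
    gene_id = c("a", "b", "c"), chrom = "chr1", strand = "+",
    tss = c(10000, 30000, 50000)
  ))
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(10499, 10500, 29000, 29100, 8100),
    end = c(10600, 10600, 29400, 29200, 8200),
    tf_name = c("TFX", "TFY", "TFX", "TFX", "TFX")
  )
  inc <- peak_incidence(prom, peaks)
  expect_true(inc$TFX[inc$gene_id == "a"])    # 1-bp overlap at window end
  expect_false(inc$TFY[inc$gene_id == "a"])   # half-open abutment
  expect_true(inc$TFX[inc$gene_id == "b"])    # two peaks count once
  expect_false(inc$TFX[inc$gene_id == "c"])

  # brute-force per-pair scan agrees
  for (i in seq_len(nrow(prom))) {
    for (tf in c("TFX", "TFY")) {
      sub <- peaks[peaks$tf_name == tf, ]
      expected <- any(vapply(seq_len(nrow(sub)), function(j) {
        overlap_bruteforce(prom$chrom[i], prom$start[i], prom$end[i],
                           sub$chrom[j], sub$start[j], sub$end[j])
      }, logical(1)))
      expect_equal(inc[[tf]][i], expected)
    }
  }
})

test_that("the one-sided enrichment p is the exact hypergeometric tail", {
  inc <- tibble::tibble(gene_id = paste0("g", 1:4),
                        TFA = c(TRUE, TRUE, FALSE, FALSE))
  labels <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    phenotype_class = rep(c("synthetic_up", "contractile_up"), each = 2)
  )
  res <- tf_enrichment(inc, labels, alternative = "synthetic_up")
  # a=2, b=0, c=0, d=2 -> C(2,2) C(2,0) / C(4,2) = 1/6
  expect_equal(res$p_one_sided, 1 / 6, tolerance = 1e-12)
  expect_equal(unlist(res[, c("a", "b", "c", "d")], use.names = FALSE),
               c(2L, 0L, 0L, 2L))

  # equal incidence proportions -> no enrichment, p >= 0.5
  inc2 <- tibble::tibble(gene_id = paste0("g", 1:8),
                         TFB = rep(c(TRUE, FALSE), 4))
  labels2 <- tibble::tibble(
    gene_id = paste0("g", 1:8),
    phenotype_class = rep(c("synthetic_up", "contractile_up"), each = 4)
  )
  res2 <- tf_enrichment(inc2, labels2, alternative = "synthetic_up")
  expect_gte(res2$p_one_sided, 0.5)

  expect_error(
    tf_enrichment(inc, tibble::tibble(gene_id = paste0("g", 1:4),
                                      phenotype_class = "synthetic_up")),
    "non-empty"
  )
})

test_that("enrichment p matches fisher.test, is monotone in a, and the two directions share the point mass", {
  set.seed(31)
  for (i in 1:40) {
    a <- sample(0:6, 1); b <- sample(0:6, 1)
    c_ <- sample(0:6, 1); d <- sample(0:6, 1)
    if (a + b == 0 || c_ + d == 0) next
    p_pkg <- lncswitch:::hypergeom_tail(a, b, c_, d)
    p_fisher <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                                   alternative = "greater")$p.value
    expect_equal(p_pkg, p_fisher, tolerance = 1e-10)
  }

  # monotone non-increasing in a at fixed margins
  margins_p <- vapply(0:4, function(a) {
    lncswitch:::hypergeom_tail(a, 4 - a, 4 - a, a)  # margins fixed at 4/4, K = 4
  }, double(1))
  expect_true(all(diff(margins_p) <= 1e-12))

  # opposite one-sided tails overlap in the observed table
  inc <- tibble::tibble(gene_id = paste0("g", 1:10),
                        TFA = c(rep(TRUE, 4), rep(FALSE, 6)))
  labels <- tibble::tibble(
    gene_id = paste0("g", 1:10),
    phenotype_class = rep(c("synthetic_up", "contractile_up"), each = 5)
  )
  both <- tf_enrichment(inc, labels)
  expect_gte(sum(both$p_one_sided), 1)
})
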