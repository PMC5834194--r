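Package: lncswitch
Title: Discovery of Long Noncoding RNAs Driving the Smooth Muscle Phenotypic Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-dataset pipeline for nominating long noncoding RNAs
    (lncRNAs) involved in the phenotypic switch of vascular smooth muscle
    cells between the proliferative "synthetic" and differentiated
    "contractile" states. Candidate lncRNAs are selected by requiring
    directionally concordant FPKM fold changes across differentiation
    datasets whose treatments push the phenotype in known (possibly
    opposite) directions, with an abundance filter, a zero-denominator
    guard and a tiered t-test significance rule. Downstream stages compare
    candidate behaviour against skeletal muscle differentiation, test
    transcription-factor ChIP-seq peak enrichment in strand-aware promoter
    windows (one-sided Fisher's exact test), correlate candidates with
    their nearest protein-coding genes (cis-acting hypothesis), and
    nominate competing-endogenous-RNA candidates from miRNA binding-site
    tracks with an inverse-expression filter. A fully deterministic
    synthetic-data generator with a planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
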