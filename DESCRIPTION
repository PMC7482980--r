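Package: trimark
Title: Co-Occurrence Analysis of DNA and Histone Modifications at Genic Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for studying combinatorial epigenetic
    marks at genes, built around the proposed trivalent mark in embryonic stem
    cells (co-enrichment of 5-hydroxymethylcytosine, H3K4me1 and H4K8ac).
    Provides peak-intensity quantification over 1-kb bins, gene bodies and
    promoter windows with counts-per-million normalization; a pairwise factor
    correlation screen (Pearson and Spearman); differential-expression
    classification of genes between cell types; ternary fold-change pattern
    classification and trivalent-mark flagging; nonnegative matrix
    factorization with multi-restart consensus clustering and cophenetic rank
    selection for gene grouping; hypergeometric over-representation analysis;
    and a synthetic-study generator with planted covariance and fold-change
    structure so every stage is verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
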