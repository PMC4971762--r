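Package: gameteprog
Title: Paternal Chromatin Programming of Embryonic Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline linking the epigenetic state of male
    gamete chromatin (histone marks, nucleosome occupancy and DNA methylation
    at promoters) to gene expression in the derived embryos. Provides
    TSS-anchored quantification of coverage tracks (metagene profiles,
    promoter levels, Poisson promoter peak calls), paired negative-binomial
    differential expression with a cross-replicate sign-consistency filter
    for calling misregulated genes, shrinkage partial-correlation network
    inference over epigenetic features and expression, chi-squared and
    hypergeometric gene-set statistics with ortholog projection, DNA-fiber
    replication-extent statistics, and a seeded synthetic-data generator that
    emulates the epigenetic programming model so that every stage is testable
    without external data.
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
    GenomicRanges,
    IRanges,
    jsonlite,
    MASS,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
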