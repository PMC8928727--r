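Package: sumenrich
Title: Sum-Based Enrichment of GWAS Signals in Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether a gene set (differentially expressed genes
    stratified by fold-change bin, or co-expression modules) is enriched
    with genome-wide association signal for a quantitative trait. Per-SNP
    effects come from a mixed-linear-model association scan (VanRaden
    genomic relationship matrix, REML variance components, EMMAX-style
    generalized least squares); the enrichment statistic is the sum of
    squared SNP effects over all SNPs inside set genes or their 5-kb
    flanks, and significance is assessed against a circular-rotation
    permutation null that preserves set size and local genomic
    clustering. Includes SNP quality control (missingness, minor allele
    frequency, exact Hardy-Weinberg test), expression filters and
    fold-change binning of differential-expression tables, a synthetic
    genotype/phenotype/expression simulator with planted enrichment for
    validation, and a YAML-configured end-to-end pipeline.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
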