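Package: amindex
Title: Assortative Mating Index for Local-Ancestry Analysis of Admixed
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects assortative and disassortative mating on local genetic
    ancestry in admixed populations. Per-gene haplotype ancestry calls
    (African, European, Native American) are compared against a triallelic
    Hardy-Weinberg null to form the assortative mating index (AMI), a log
    odds ratio of observed-to-expected ancestry homozygosity versus
    heterozygosity. Gene-level indices are pooled over polygenic-phenotype
    gene sets with Mantel-Haenszel fixed-effects meta-analysis, with
    Benjamini-Hochberg false discovery control, random-mating and
    random-gene-set permutation nulls, per-ancestry driver decomposition,
    and a forward-in-time simulator of admixed populations with tunable
    mate-matching strength for validation and power studies.
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
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
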