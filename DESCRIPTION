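Package: sdrscan
Title: Comparative Analysis of Sex-Determining-Region Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for comparative analysis of phased
    sex-determining-region (SDR) haplotypes in dioecious plants such as wild
    grape. Provides anchor-based whole-haplotype alignment with SNP,
    small-INDEL and structural-variant calling; strict sex-linkage
    classification across a male/female/hermaphrodite haplotype panel;
    coding-consequence annotation including frameshift truncation and
    in-silico PCR marker assays; per-gene neighbor-joining phylogenies with
    bootstrap, a sex-monophyly test and changepoint localization of the
    hermaphrodite recombination breakpoint; Nei-Gojobori synonymous-distance
    estimation with molecular-clock dating; windowed linkage-disequilibrium
    tracks; F1 segregation tests; sex-specific expression-pattern
    classification; and promoter motif scanning. A built-in simulator
    generates SDR haplotype panels with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    DESeq2,
    S4Vectors,
    withr
Config/testthat/edition: 3
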