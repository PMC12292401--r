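Package: capriscan
Title: SNP-Array Population Genomics: Inbreeding, Structure and Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for population-genomic analysis of
    diploid SNP-array genotypes in livestock: quality control (call rates,
    exact Hardy-Weinberg testing, minor allele frequency, LD pruning,
    identity-by-state duplicate removal), genetic structure (PCA, an
    EM-fitted admixture model with masked-entry cross-validation, observed
    homozygosity, rank-sum comparisons), consecutive-SNP runs of
    homozygosity and F_ROH inbreeding, linkage-disequilibrium decay and
    Sved-equation effective population size, and haplotype-based selection
    scans (EHH, iHS, Rsb) with sliding-window rank p-values and
    candidate-region calling. Includes a Balding-Nichols mosaic-of-founders
    simulator that generates phased, structured genotype data with planted
    autozygosity and selective sweeps so the whole pipeline is testable
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    withr,
    generics,
    data.table,
    vcfR,
    fgsea,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
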