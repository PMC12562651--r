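Package: pairedgwas
Title: Association Testing for Paired Tumor-Normal Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association analysis for matched tumor-normal
    designs, where each patient contributes a germline and a tumor genotype
    at every SNP. Models the 3x3 table of paired genotypes as a multinomial
    distribution parameterized by the somatic relative risk, the risk allele
    frequency and the per-allele somatic mutation rate. Provides penalized
    maximum-likelihood estimation with Wald, score and likelihood-ratio tests
    of no association; a hierarchical Bayesian model for single markers and
    SNP sets (genes or gene segments) fitted by Gibbs-within-Metropolis
    MCMC; a simulator for power and type I error studies; and genome-scale
    helpers for quality control, SNP-to-gene mapping and even segmentation
    of long genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    Rcpp,
    generics,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
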