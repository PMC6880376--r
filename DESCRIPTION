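Package: sweepkit
Title: Selective Sweep Scans from Diploid Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for detecting selective sweeps in diploid
    population resequencing data. Implements windowed nucleotide diversity
    and Tajima's D, Weir-Cockerham FST variance components with weighted
    window estimates, EHH12/iHH12 haplotype homozygosity, pairwise linkage
    disequilibrium (D, D', r2) and LD decay, PLINK-style runs of
    homozygosity with F_ROH, and a composite empirical-outlier scan
    (top-tail thresholds, three-statistic intersection, region merging and
    gene annotation). Includes a forward Wright-Fisher simulator with
    optional hard sweeps for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Rcpp,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
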