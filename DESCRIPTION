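Package: zeascan
Title: Population-Genomic Scans for Maize Domestication and Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for population-genomic analysis of
    maize and its teosinte relatives: cohort simulation under a
    Balding-Nichols population tree with planted selective sweeps and
    flowering-time-like phenotypes; genotype QC and per-SNP statistics
    (MAF, polymorphic information content); structure diagnostics (GRM
    PCA, identity-by-state distances, neighbor-joining trees, Q-matrix
    group assignment); 50-kb window haplotype sharing, rarefaction
    richness and shared-ancestry categories; Weir-Cockerham windowed FST
    and an XP-CLR-style composite-likelihood sweep scan with
    quantile-based sweep calling; permutation tests for sweep-GWAS-signal
    co-localization; and a P3D mixed-linear-model association scan with
    LD pruning and Bonferroni thresholding.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
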