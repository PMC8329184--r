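Package: phewasMR
Title: Phenome Scans and Mendelian Randomization for Metabolite Biomarkers
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A virtual-biomarker toolkit for dissecting the genetic
    architecture of a plasma metabolite from GWAS summary statistics and
    EHR-style phenome data. Builds independent genetic instruments by
    greedy LD clumping with cohort-level QC, converts ICD event streams
    into phecode case/control cohorts, scans the phenome with single-SNP
    and polygenic-score logistic regressions, combines cohorts by
    METAL-style sample-size-weighted or inverse-variance meta-analysis
    with Benjamini-Hochberg FDR control, and runs bi-directional
    two-sample Mendelian randomization (inverse-variance weighted,
    MR-Egger, weighted median, with Cochran's Q heterogeneity). A seeded
    synthetic-data generator emulates LD-block genotypes, a heritable
    metabolite, binary diseases under a configurable causal graph with
    horizontal pleiotropy, ICD event streams and two-sample summary
    statistics, providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
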