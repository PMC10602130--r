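Package: feiscan
Title: Mixed-Model Genetic Analysis of Baseline FVIII-Inhibitor Status in
    Hemophilia A
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variance-component and association analysis of binary
    FVIII-inhibitor status in hemophilia A cohorts with related subjects
    and heterogeneous causative F8 mutations. Builds an empirical genomic
    relationship matrix and a shared-causative-mutation covariance matrix,
    fits a binary linear mixed model with both structured random effects
    by REML, partitions heritability with boundary-corrected likelihood
    ratio tests, runs a gene-centric association scan with per-gene and
    chip-wide Bonferroni thresholds, fits joint logistic odds-ratio models
    with BIC selection over race-by-SNP interaction subsets, and simulates
    pedigreed synthetic cohorts with a liability-threshold phenotype so the
    whole pipeline is testable without restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
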