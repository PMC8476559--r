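Package: mrcCNV
Title: Copy-Number Genotyping and Case-Control Association for
    Competitive PCR Assays
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for gene copy-number determination from competitive-PCR
    peak-height ratios (median standardization to sCN, half-open binning to
    digitized copy numbers), droplet digital PCR quantification by Poisson
    partition statistics with cross-reactive cluster gating, case-control
    association testing on copy-number categories (Fisher exact and Pearson
    chi-squared on 2xk tables, odds ratios with zero-cell lower-bound
    policies, Bonferroni correction), and Hardy-Weinberg equilibrium testing
    for unphased diploid copy-number data via EM estimation of haplotype
    copy-class frequencies with asymptotic and parametric-bootstrap
    p-values. Includes a synthetic cohort generator that simulates
    Hardy-Weinberg genotypes, case enrichment at a target odds ratio, and
    both measurement processes, so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
biocViews: CopyNumberVariation, GeneticVariability, StatisticalMethod,
    ddPCR, Genetics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
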