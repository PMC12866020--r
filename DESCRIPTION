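Package: liverEWAS
Title: Blood DNA Methylation and Liver Steatosis: EWAS, Meta-Analysis,
    meQTL Conditioning and Expression-Mediated Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a multi-cohort epigenome-wide
    association workflow linking whole-blood DNA methylation to liver-steatosis
    indicators. Covers phenotype derivation (fatty liver index, rank-based
    inverse-normal transformation, alcohol and BMI categorisation), per-CpG
    covariate-adjusted association models with genomic-inflation diagnostics
    and empirical-null (bias/inflation) correction of test statistics,
    inverse-variance fixed-effect meta-analysis with a multi-cohort
    replication rule, cis-meQTL discovery with top-variant conditional models,
    expression-quantitative-trait-methylation (eQTM) scans, and
    product-of-coefficients mediation with Delta-method standard errors and
    BMI-stratified reporting. Ships a synthetic multi-cohort, multigenerational
    data generator with planted ground-truth effects for parameter-recovery
    testing, plus TSV/VCF/BED/JSON readers and writers and a deterministic
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
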