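Package: mtgblup
Title: Multi-Trait Genomic Prediction for Multi-Environment Plant Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for multi-trait, multi-environment genomic prediction
    in biparental crop populations. Covers simulation of connected doubled-
    haploid families with known genetic architecture, estimation of genotype
    BLUEs and Cullis heritability from plot-level data by EM-REML, SNP quality
    control and the VanRaden realized additive relationship matrix, single-trait
    and multi-trait Bayesian GBLUP fitted by Gibbs sampling with a Kronecker
    trait-by-kinship covariance, and CV1/CV2 cross-validation schemes for
    comparing the predictive ability of trait-set strategies, including
    prediction into un-phenotyped environments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
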