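Package: prsgxe
Title: Polygenic Score by Environment Interaction Analysis for Family Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of polygenic risk score (PRS) by environment
    interactions for childhood adiposity outcomes in family-structured cohorts
    with repeated measurements. Implements genome-wide PRS construction
    (effect-allele harmonization, LDpred-inf shrinkage, clumping and
    thresholding, genome-wide-significant subsets), genetic relatedness
    matrices, kinship-aware linear mixed models fitted by restricted maximum
    likelihood through a single eigendecomposition, penalized quasi-likelihood
    logistic mixed models, Wald interaction tests with Benjamini-Hochberg
    false-discovery-rate adjustment, stratified PRS slopes, and anthropometric
    phenotype derivation (LMS z-scores, age- and sex-specific cutoffs, diet
    and activity scores). A family-cohort simulator with known ground truth
    (LD-blocked genotypes, gene-dropping, point-normal causal architecture,
    true interaction effects) supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
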