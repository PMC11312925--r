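Package: glycotwin
Title: Twin-Cohort Immunoglobulin Glycomics: Heritability, Enzymatic
    Ratios and Kinship-Aware Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of immunoglobulin
    glycopeptide panels in twin cohorts. Implements peptide-wise
    compositional normalisation of glycoform intensities, outlier
    masking, rank-based inverse-normal transformation and configurable
    derived glycosylation traits; maximum-likelihood univariate
    (ACE/AE/CE/E) and bivariate twin variance decomposition with AIC
    model selection, genetic/environmental covariance and shared
    heritability; product/substrate conversion-rate ratios along
    enzymatic reaction chains in glycoform composition space; mixed-model
    association of traits with age and sex, the Li-Ji effective number
    of independent tests, and residual correlation networks; and a
    kinship-aware linear mixed-model GWAS with genomic-control
    diagnostics, stepwise conditional scans, replication verdicts and
    SNP-based variance explained. A synthetic twin-cohort generator with
    known ground-truth variance components, SNP effects and covariate
    effects makes every stage testable without access to managed
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
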