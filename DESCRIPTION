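Package: famvar
Title: Familiality and SNP Heritability of Depression Subphenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-track heritability analysis for quantitative subphenotypes of
    major depressive disorder (age at onset and episode frequency) measured in
    affected-sibling families and in unrelated genotyped cases.  Track one
    estimates familial aggregation with nested linear mixed models and a
    negative-binomial mixed model for episode counts (adaptive Gauss-Hermite
    quadrature), summarised as intraclass correlations with delta-method
    confidence intervals, including a variance-decomposition ICC for
    overdispersed counts, and converts sibling ICCs into maximal-heritability
    upper bounds.  Track two estimates SNP heritability with a self-contained
    GREML engine: genetic relationship matrix construction from PLINK
    genotypes, relatedness pruning, principal-component covariates, AI-REML
    with boundary-corrected likelihood-ratio tests, plus analytic power and
    detectable-effect calculations.  A synthetic-data module generates family
    phenotype tables and genotype panels with known ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    MASS,
    withr
Config/testthat/edition: 3
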