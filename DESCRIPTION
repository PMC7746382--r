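Package: gcctwin
Title: Generalized Correlation Coefficient Association Testing for Twin GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric genome-wide association testing with the generalized
    correlation coefficient (GCC), a density-ratio generalized R-squared for
    genotype-phenotype dependence with a cross-validation likelihood-ratio
    statistic and permutation-calibrated p-values, alongside twin-aware linear
    comparators (kinship-matrix generalized least squares and a pair-level
    random-intercept mixed model). Includes dosage VCF and text-matrix readers
    with post-imputation variant filters, a scan engine with covariate
    adjustment, Box-Cox normalization and genomic-inflation reporting, and a
    twin simulator (Hardy-Weinberg genotypes, Mendelian transmission, shared
    pair environments) for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
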