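Package: domgp
Title: Genomic Prediction and Association Analysis with Dominance Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dominance-aware genomic analysis for biallelic SNP panels:
    construction of additive (G) and dominance (D) genomic relationship
    matrices from PLINK bed/bim/fam genotypes, two-component restricted
    maximum likelihood (GBLUP and GBLUP-D) with average-information updates
    and likelihood-ratio model comparison, BayesA/BayesAD Markov chain Monte
    Carlo marker-effect models with per-marker scaled inverse chi-square
    variances, multi-locus mixed-model association scans with additive and
    dominance codings, repeated k-fold cross-validation of predictive
    ability, and a synthetic genotype/phenotype generator with known
    additive and dominance architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
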