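Package: spruceGS
Title: Multi-Trait Genomic Selection for Pest Resistance, Growth and Wood
    Quality in Forest-Tree Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genomic selection in progeny-tested
    forest-tree breeding populations: pedigree (A) and VanRaden genomic (G)
    relationship matrices with SNP quality control and LD-kNN imputation;
    REML individual-tree ("animal") mixed models for heritability, type-B
    genetic correlations and breeding values; bivariate and multi-trait GBLUP
    with missing phenotypes; Gibbs-sampled whole-genome regressions (Bayesian
    ridge regression, BayesC-pi) and a threshold GBLUP for ordinal traits such
    as cumulative weevil-attack counts; family-stratified cross-validation
    with predictive ability and accuracy; and selection-index optimisation of
    multi-trait genetic gains. Includes a gene-drop simulator of partial-diallel
    populations for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
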