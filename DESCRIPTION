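Package: grsbench
Title: Benchmarking Whole-Genome Risk Prediction for Case-Control Disease Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for building and benchmarking genomic risk
    scores on case-control data. Implements four whole-genome predictors
    (p-value-thresholded genetic profile risk scores, GBLUP via REML variance
    components, elastic-net penalized regression with SNP pre-selection, and a
    Bayesian four-component normal-mixture regression fitted by Gibbs
    sampling), the surrounding quality-control, relatedness-pruning and
    ancestry-adjustment stages, cross-validated AUC evaluation, decile
    odds-ratio risk stratification, and expected odds ratios under the
    liability-threshold model. Ships a synthetic genotype-phenotype generator
    (mixture genetic architectures, liability-threshold case-control
    ascertainment, population stratification, batch artifacts) so the whole
    pipeline is testable without restricted cohort data, plus readers and
    writers for PLINK text and binary genotype formats and GCTA-style
    relationship matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
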