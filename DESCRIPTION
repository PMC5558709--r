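Package: flockQTL
Title: Genomic Prediction and Pleiotropic QTL Mapping in Structured Sheep Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trait mixed-model association analysis, genomic prediction
    (GBLUP and a four-component BayesR mixture fitted by Gibbs sampling), and
    three multi-trait procedures for mapping pleiotropic quantitative trait
    loci: a chi-square statistic combining signed t-values across traits, the
    product of BayesR posterior null probabilities, and eigen-analysis of
    standardized local breeding-value covariance in 250-kb genomic windows.
    Includes cross-validation by paternal half-sib family, a linear selection
    index for independent validation of SNP effects, conditional-normal
    imputation of missing phenotypes, an analytical false discovery rate
    estimator, genotype quality control and file I/O, and a gene-dropping
    simulator of multi-trait half-sib populations with known pleiotropic QTL
    that makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
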