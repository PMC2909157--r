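Package: multibreed
Title: Multibreed Maternal Animal Models with Breed-of-Origin Covariance
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multibreed maternal animal models for crossbred pedigrees in
    which the additive genetic covariance is decomposed by breed origin into
    partial numerator relationship matrices (one per parental breed plus a
    segregation term). Provides pedigree handling with expected breed fractions
    and heterosis covariates, tabular and row-wise construction of the partial
    relationship matrices and their collapsed sparse inverses over contributing
    animals, BLUP of direct and maternal breeding values with reconstruction of
    total breeding values, a single-site systematic-scan Gibbs sampler for all
    eleven (co)variance components under conjugate inverse-Wishart and scaled
    inverse chi-squared priors, posterior summaries (kernel-density modes,
    highest-posterior-density intervals, effective sample sizes) and derived
    genetic parameters (source-wise variance partitions, heritabilities and the
    direct-maternal correlation for a reference breed group), plus a
    crossbred-design simulator and a gene-dropping oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
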