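Package: bifactorPRS
Title: Polygenic Risk Scores and Latent Psychopathology Factors in
    Ordinal Bifactor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links polygenic risk scores to adolescent psychopathology
    modelled as latent factors measured by ordinal questionnaire items.
    Provides polygenic scoring from discovery genome-wide association
    summary statistics (P-value thresholding, allele harmonization,
    standardization), limited-information estimation of four competing
    measurement structures (uncorrelated, unidimensional, correlated
    factors, bifactor) via polychoric correlations and diagonally
    weighted least squares with mean-and-variance adjusted fit
    statistics, marginal-likelihood information criteria by quasi-Monte
    Carlo integration, model-based omega reliability coefficients,
    simultaneous latent-factor-on-score regression with permutation
    family-wise adjusted inference and inverse-probability weighting
    for selective missingness, and a synthetic-data generator that
    reproduces the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
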