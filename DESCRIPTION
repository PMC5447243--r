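Package: fieldfit
Title: Modeling Transcriptome Dynamics Under Fluctuating Field Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-wise statistical modeling of transcriptome dynamics in
    field environments. Expression of each gene is regressed on the plant's
    age, a sine/cosine circadian-clock basis, genotype, and a nonlinear
    environmental-response feature that integrates a thresholded,
    saturating response to a meteorological factor through a 24-h periodic
    gate over a gene-specific memory period. Variable selection uses an
    adaptive group lasso with an efficient approximate leave-one-out
    cross-validation and the 1-SE rule. Includes RNA-Seq support via
    log-cpm precision weights, cluster-based warm-start optimization using
    affinity propagation, a negative-binomial synthetic-data benchmark
    with realistic field sampling designs, synthetic meteorological
    series, and model-recovery evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
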