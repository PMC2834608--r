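Package: ssgblup
Title: Single-Step Genomic Prediction for Partially Genotyped Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-step genomic BLUP for populations in which only a subset
    of animals is genotyped. Builds the pedigree numerator relationship
    matrix and its sparse inverse, the marker-based genomic relationship
    matrix and its pedigree extension to non-genotyped animals, blends the
    two with a polygenic weight, estimates variance components by average
    information REML with a profile likelihood over the polygenic weight,
    and computes BLUP breeding values with prediction error variances.
    Includes a stochastic simulator of a pig nucleus breeding program for
    method validation, and a three-method comparison (one-step, pedigree
    BLUP, two-step) of prediction accuracy.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
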