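Package: chronotopy
Title: Temporal Cohorts and Chronotopic Maps of the Spinal Dorsal Horn
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative pipeline for establishing temporal cohorts and the
    chronotopic organization of spinal dorsal horn interneurons:
    landmark-based normalization of section coordinates onto an idealized
    spinal cord template, cumulative EdU birthdating curves with sigmoid
    (logistic/4PL/5PL) inflection statistics, dynamic-time-warping
    permutation tests on composition-versus-time and ranked-expression
    curves, and spatial quantification via 2D kernel density estimates with
    highest-density contour levels, dorsoventral depth histograms and
    quintile ANOVA. Includes synthetic-data generators that emulate every
    input with known ground truth so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
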