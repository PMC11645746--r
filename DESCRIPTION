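Package: vfarchetypes
Title: Archetypal Analysis of Visual Field Loss Patterns Across Perimetric Stimulus Sizes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for unsupervised decomposition of standard automated
    perimetry visual fields into archetypal loss patterns. Implements the
    full pipeline for comparing Goldmann stimulus sizes III and V on the
    24-2 grid: censoring of noise-dominated sensitivities (21 dB for size
    III, 24 dB for size V), age standardization to total deviation against
    a parametric normative model, exclusion of high false-positive tests,
    archetypal analysis by simplex-constrained alternating least squares
    with furthest-sum initialization and restarts, 10-fold cross-validated
    selection of the number of archetypes, decomposition of fields onto a
    fixed archetype map with relative weights normalized to 100%, greedy
    cosine-similarity pairing of archetype maps, combined-stimulus
    analysis, and Wilcoxon signed-rank comparison of relative weights. A
    synthetic-data generator produces paired size III/V datasets as convex
    mixtures of ground-truth archetypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
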