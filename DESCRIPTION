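Package: spanr
Title: Marker-Gene-Informed Spatial Annotation of Spatially Resolved Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Probabilistic assignment of spots or cells in spatially resolved
    transcriptomics (SRT) data to predefined cell or domain types using
    a negative-binomial mixture over marker genes combined with a hidden
    Markov random field (Potts-like) spatial prior. Model fitting alternates
    expectation-maximization for the mixture, pseudolikelihood estimation of
    the spatial field, and iterated conditional modes for label updates.
    Includes a Splatter-style synthetic SRT generator with layered spatial
    domains, marker derivation and corruption utilities, spatial-noise and
    batch-effect injection, and evaluation metrics (accuracy, macro F1,
    multiclass Matthews correlation coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
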