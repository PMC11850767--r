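Package: competedyn
Title: Competitive Behavior and Hippocampal Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of competitive behavior and ventral-
    hippocampal population dynamics: pose-derived behavior featurization
    and motif clustering, peri-event unit responsiveness, cross-day unit
    tracking by waveform and interspike-interval similarity, recurrent
    switching linear dynamical system (rSLDS) modelling of binned
    population rates, rotational-dynamics and attractor metrics,
    state-specific multinomial GLM behavior decoding, and longitudinal
    lagged cross-correlation.  Ships a synthetic-data generator with
    known ground truth so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
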