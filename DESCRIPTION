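Package: gazecnn
Title: Convolutional Neural Network Analysis of Visual-Search Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies the screen location of search targets and
    task-irrelevant distractors from raw gaze time courses recorded during
    visual search, using a one-dimensional convolutional neural network
    trained with mini-batched cross-entropy, Adam updates, exponential
    learning-rate decay and early stopping. Provides frequentist accuracy
    summaries (participant-level bootstrap confidence intervals, t-tests
    against chance and against a first-saccade landing heuristic), a
    hierarchical binomial-beta model of participant-level accuracy sampled
    by MCMC, additive feature attribution with an exact completeness
    guarantee, rotation-aligned kernel density maps of the most informative
    gaze samples, and a synthetic gaze-data generator that emulates
    target-directed and distractor-captured saccades for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rjags,
    stats,
    utils
Suggests:
    coda,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
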