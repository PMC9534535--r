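Package: numspike
Title: Number Tuning in an Untrained Spiking Network with Lateral Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a two-layer current-based leaky integrate-and-fire
    spiking network with distance-dependent lateral inhibition and random,
    untrained feedforward weights, and analyses the numerosity and digit
    tuning of its output units. Provides generators for non-symbolic
    numerosity stimuli (dot displays) and a synthetic handwritten-digit
    fixture, a Bernoulli rate-coding spike encoder, a fast simulation core,
    and tuning-curve analyses: preferred-class distributions, averaged
    normalized tuning curves, and Gaussian fits on linear, square-root,
    cube-root and log2 abscissae with goodness-of-fit and bandwidth
    summaries.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
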