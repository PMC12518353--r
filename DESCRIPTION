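Package: samplefence
Title: Simulation and Hierarchical Bayesian Analysis of Binned Sampling Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how people allocate a fixed sampling budget
    over the bins of a known histogram when estimating the mean of a hidden,
    scaled distribution. Implements the binned-beta "star rating" task
    environment (exact bin probabilities, within-bin moments, truncated-beta
    draws), simulated sampling agents including a proportional stratified
    baseline and a cognitive-fencing mixture policy f = (1-w)*g + w*u,
    preregistered exclusion rules, sampling-bias and estimation-adjustment
    statistics with cluster bootstrap intervals, pooled exact binomial tests of
    allocation shares, stratified-sampling efficiency calculations, and
    hierarchical Bayesian inference of the mixture weight w by adaptive
    Markov chain Monte Carlo with convergence diagnostics and a
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
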