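Package: serialcp
Title: Serial Dependence and Choice Probability Analysis for Sensory Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether serial dependencies in perceptual choices
    and in sensory-neuron spike counts account for choice probabilities.
    Implements history-aware probit choice models with lasso regularization,
    Poisson spike-count models with a Gaussian-process latent for slow firing
    rate fluctuations, semipartial choice probabilities, an independent
    observer control, autoregressive choice-spike simulators with
    moment-matching fits and a power analysis, and a synthetic session
    generator that emulates pseudorandomized disparity-discrimination
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    magrittr,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
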