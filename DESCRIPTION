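Package: brainsem
Title: Collider-Aware Inference for Relative Brain Size as a Predictor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and inference toolkit for comparative analyses in
    which relative brain size (brain size beyond the allometric expectation
    for body size) appears either as a response or as a predictor variable.
    Provides generative simulators for both causal structures, closed-form
    multiple regression fits, Bayesian linear models and a Bayesian
    structural equation model (fitted with JAGS) that estimates relative
    brain size inside the sampler, and a Monte-Carlo experiment runner that
    scores bias and coverage of each estimator. Demonstrates that multiple
    regression on absolute brain size plus body size conditions on a
    collider and misestimates the direct body-size effect, while the
    structural equation model recovers it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
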