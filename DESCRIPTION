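Package: ggwpem
Title: EM Hyperparameter Optimisation for Bayesian Linear Regression with
    General Gaussian Weight Priors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evidence-based (type-II maximum likelihood) hyperparameter
    optimisation for Gaussian linear basis-function regression under a
    general Gaussian weight prior with a separate precision and prior mean
    for every weight.  Provides the closed-form weight posterior, the log
    marginal likelihood (evidence), an EM algorithm that alternates
    posterior-moment computation with re-estimation of the per-weight
    precisions, prior means and noise precision, a seeded synthetic-data
    generator matching the model's generative assumptions, and a
    global-best particle swarm optimiser over the same evidence objective
    as a baseline.  The zero-mean relevance vector machine prior is
    available as a restricted mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
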