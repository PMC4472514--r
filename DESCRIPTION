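Package: rwsens
Title: Sensitivity of Model-Based Regression to the Reinforcement Learning Rate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Quantifies how model-based regression analyses of learning
    signals (as used in model-based fMRI) depend on the Rescorla-Wagner
    learning rate. Provides closed-form correlations between value and
    prediction-error regressors generated with different learning rates,
    under fixed and drifting (mean-reverting random walk) reward
    distributions; the induced regression coefficients, t statistics and
    Gaussian log-likelihood profiles for misspecified regressors; grid
    evaluations over learning-rate and design-parameter space, including
    an insensitivity metric for experiment design; and Monte-Carlo
    validation of every closed form against simulation of the generative
    processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
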