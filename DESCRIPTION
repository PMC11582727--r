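Package: foragefit
Title: Dynamic-Foraging Task Simulation and Linear-Nonlinear-Probabilistic
    Choice Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-option dynamic-foraging (matching-law) task with
    baited rewards and a change-over delay, together with an instruction-based
    control task, and fits the linear-nonlinear-probabilistic (LNP) model of
    value learning and choice: Wiener-Hopf estimation of the linear reward
    filter, exponential-decay approximation of its weights, trial-by-trial
    subjective values, and a cumulative-normal choice-probability function.
    Includes behavioural evaluation (matching, harvest rate, switch rate,
    leave-one-out choice prediction) and construction of HRF-convolved,
    serially orthogonalized parametric value regressors for fMRI general
    linear models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
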