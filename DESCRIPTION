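Package: pavlearn
Title: Trial-by-Trial Learning Models and Bayesian Model Selection for
    Pavlovian Threat Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing trial-by-trial associative learning models
    against single-trial autonomic response amplitudes (skin conductance or
    pupil size) from discriminant Pavlovian threat conditioning experiments.
    Implements Rescorla-Wagner, hybrid Rescorla-Wagner/Pearce-Hall,
    beta-binomial Bayesian ideal-observer, and non-learning null models,
    each linked to measured amplitudes through a linear observation function.
    Models are fitted per participant by residual-sum-of-squares minimisation
    on trials without reinforcement, compared by the Bayesian Information
    Criterion, and selected at the group level with random-effects Bayesian
    model selection, including protected exceedance probabilities and family
    inference. A synthetic-data generator emulating the discriminant
    conditioning design and a simulated model-recovery analysis (confusion
    matrices over models and families) support design validation, alongside
    linear mixed-effects manipulation checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
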