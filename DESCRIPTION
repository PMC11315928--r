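Package: serocog
Title: Computational Modelling of Valence-Specific Learning and Response
    Inhibition in Placebo-Controlled Serotonin Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for two-visit, placebo-controlled
    behavioural pharmacology studies of serotonergic agents. Implements a
    valence-specific reinforcement-learning model (separate win/loss learning
    rates and outcome sensitivities) for probabilistic instrumental learning
    tasks, a five-parameter drift-diffusion model for deadline-censored
    affective go/no-go tasks fitted by quantile-binned G-squared maximum
    likelihood, signal-detection indices (d-prime, criterion c), and the
    study-level statistical layer: baseline-adjusted mixed ANCOVA with
    estimated-marginal-mean contrasts, Holm correction, Cohen's d and partial
    eta-squared with confidence intervals, longitudinal REML mixed models and
    chi-square tests. A synthetic-cohort generator with known ground truth
    supports end-to-end parameter-recovery and calibration studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nlme,
    emmeans,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
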