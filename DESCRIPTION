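Package: hybridec
Title: Causal Inference for Hybrid Trials with External Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the average treatment effect in hybrid clinical
    trials that augment a randomized trial with an external control arm.
    Implements outcome-model (g-computation), inverse probability of data
    source weighting (IPDW), augmented inverse probability weighting (AIPW),
    and targeted maximum likelihood (TMLE) estimators with cross-fitted
    parametric or random-forest nuisance models, influence-curve and
    bootstrap confidence intervals, covariate-balance and
    mean-exchangeability diagnostics, tipping-point sensitivity analysis,
    selection single-world intervention graphs with d-separation checks of
    the borrowing assumption, and a simulation engine for evaluating bias,
    coverage, type-I error, and power.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
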