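# hybridec

Causal inference for **hybrid clinical trials**: randomized trials whose
control arm is augmented with **external controls** (a historical trial
arm, a registry, or EHR patients meeting the trial's eligibility
criteria). The package is aimed at trial statisticians and
methodologists who want to borrow external control information *with*
an explicit causal contract, honest diagnostics, and machine-learning
nuisance models that keep valid confidence intervals.

## The problem and the model

The observed data are iid copies of O = (Y, X, A, D): outcome,
baseline covariates, randomized treatment (with known within-trial
randomization probability π_a), and source indicator (D = 1 trial,
D = 0 external; external subjects are all controls). The target is the
average treatment effect in the study population,

    τ = E[Y¹ − Y⁰ | D = 1].

Because source membership is not randomized, identification needs a
borrowing assumption — *mean exchangeability across sources*:
E[Y⁰ | X, D = 1] = E[Y⁰ | X, D = 0] for some measured covariate set X.
Then τ = E[Y | A = 1] − E_{X|D=1}[ E(Y | A = 0, X) ], and the package
provides:

* **Selection SWIGs** — causal DAGs with selection nodes marking
  conditionals that may differ between populations and the treatment
  node split under the control intervention; `check_a4()` verifies the
  borrowing assumption by d-separation, `minimal_adjustment_sets()`
  enumerates sufficient adjustment sets.
* **Four estimators** of τ plus an RCT-only comparator: g-computation
  (`estimate_tau_om`), inverse probability of data-source weighting
  (`estimate_tau_ipdw`), and the doubly robust AIPW
  (`estimate_tau_aipw`) and TMLE (`estimate_tau_tmle`) built on the
  efficient influence curve

      φ(O) = (1/q) { D[m₁ − m₀ − τ] + (DA/π_a)[Y − m₁] − W^dr [Y − m₀] },

  with cross-fitted nuisance models (linear/logistic or random
  forests), closed-form influence-curve intervals for AIPW/TMLE, and
  stratified nonparametric bootstrap intervals for the singly robust
  methods.
* **Diagnostics & sensitivity analysis** — normalized covariate
  difference, study-propensity imbalance (0.25 reference flag), a
  binned visual check of mean exchangeability, a plug-in estimate of
  the asymptotic bias under violations, and a closed-form tipping-point
  magnitude.
* **A simulation engine** reproducing the hybrid-trial study design
  (150 trial patients randomized 2:1, 50 external controls) with
  configurable nuisance-model misspecification, for
  bias/MSE/coverage/type-I/power evaluation.

## Worked example

```r
library(hybridec)

# a synthetic hybrid trial: 150 RCT subjects (2:1), 50 external controls
dat <- simulate_trial(sim_config(setting = 1, tau = 1), seed = 5)
dat
#> Hybrid-trial data: n = 200 (150 trial, 50 external controls)
#>   treated: 109  internal controls: 41
#>   covariates: x1, x2, x3, x4
#>   design Pr(A=1|D=1) = 0.6667

fits <- fit_nuisances(dat, learner_spec(), k_folds = 10, seed = 2)
estimate_tau_aipw(dat, fits)
#> AIPW estimate of the average treatment effect
#>   tau = 1.129  (se 0.151)
#>   95% CI (0.8327, 1.425)   p = 7.68e-14
#>   n_rct = 150, n_ec = 50

estimate_tau_rct(dat, fits)   # no-borrowing comparator
#> RCT_AIPW estimate of the average treatment effect
#>   tau = 1.104  (se 0.1682)
#>   95% CI (0.7746, 1.434)   p = 5.18e-11
#>   n_rct = 150, n_ec = 0
```

The true effect here is 1. Borrowing the 50 external controls shrinks
the standard error from 0.168 to 0.151 (a ~19% narrower interval) while
the point estimates agree — the efficiency gain that motivates the
design. The graphical side:

```r
g <- load_graph(system.file("extdata", "sma_graph.txt", package = "hybridec"))
swig <- build_selection_swig(g,
  differing_covariates = c("Age", "Type", "Scoliosis", "MFM0"))
check_a4(swig, c("Age", "Type", "Scoliosis", "MFM0"))$holds
#> [1] TRUE
check_a4(swig, c("Type", "Scoliosis", "MFM0"))$holds   # Age omitted
#> [1] FALSE
```

A command-line surface wraps the same functions
(`inst/cli/hybridec`): subcommands `estimate`, `diagnose`, `simulate`,
`power`, `swig-check`.

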