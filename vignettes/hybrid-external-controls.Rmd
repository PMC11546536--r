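---
title: "Estimating treatment effects in hybrid trials with external controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating treatment effects in hybrid trials with external controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridec)
```

## The setting

A hybrid trial analyzes a randomized controlled trial together with an
external control arm: control-treated patients drawn from outside the
trial (a historical trial arm, a registry, or EHR data) who meet the
trial's eligibility criteria. The observed data are iid copies of
$O = (Y, X, A, D)$: a continuous (or binary) outcome $Y$, baseline
covariates $X$, a binary treatment $A$ (randomized within the trial with
known probability $\pi_a$), and a source indicator $D$ ($D = 1$ for the
trial, $D = 0$ for external controls, who all have $A = 0$).

The target parameter is the average treatment effect in the study
population, $\tau = E[Y^1 - Y^0 \mid D = 1]$, which here coincides with
the treatment effect among the treated because external subjects are
never treated and treatment is randomized inside the trial.

Identification rests on four assumptions: consistency of the potential
outcomes, exchangeability and positivity of treatment assignment within
the trial (guaranteed by randomization), and *mean exchangeability
across sources*: for some measured covariate subset $X$,
$E[Y^0 \mid X, D = 1] = E[Y^0 \mid X, D = 0]$. The last is the borrowing
assumption; everything nonstandard about hybrid trials flows from it.
Under these,
$$\tau \;=\; E[Y \mid A = 1] \;-\; E_{X \mid D=1}\!\big[E[Y \mid A = 0, X]\big].$$

## Reasoning about the borrowing assumption graphically

Whether mean exchangeability is plausible depends on the causal
structure. The package represents the investigator's causal DAG
(`causal_graph()`, `load_graph()`) and builds a *selection SWIG*
(`build_selection_swig()`): the treatment node is split into a random
half (keeping incoming edges) and a fixed half set to control (keeping
outgoing edges), making the counterfactual control outcome an explicit
node, and a selection node $S_Z \to Z$ is added for every covariate
whose distribution the investigator declares as possibly differing
between the study and external populations (plus $S_Y \to Y$ if the
outcome mechanism itself may differ). The borrowing assumption holds for
an adjustment set $X$ exactly when the counterfactual outcome is
d-separated from every selection node given $X$ (`check_a4()`,
`d_separated()`, `minimal_adjustment_sets()`).

Two design choices deserve note. First, which conditionals differ
across populations is not computable from the observed data, so the
construction takes *declarations*; declaring a selection node on every
covariate is the conservative model and the default worth recommending.
Second, the fixed treatment half is a constant, so the d-separation
routine treats it as blocking every path through it; the Bayes-ball
reachability algorithm is used, and the test suite checks it
exhaustively against a path-enumeration oracle on random DAGs of up to
eight nodes. Supersets of a valid adjustment set are *not* automatically
valid (conditioning can open colliders); a regression test encodes one
such graph.

## Estimators

Write $m_a(x) = E[Y \mid A = a, X = x]$,
$\pi_d(x) = \Pr(D = 1 \mid X = x)$ (the study propensity score), and
$\pi_a(x) = \Pr(A = 1 \mid X = x, D = 1)$ (known by design). Four
estimators of $\tau$ are provided, plus an RCT-only comparator
(`estimate_tau_rct()`, standard within-trial AIPW).

**Outcome model / g-computation** (`estimate_tau_om()`):
$\widehat\mu_{0,om} = n_{rct}^{-1} \sum_i D_i\, \widehat m_0(X_i)$ with
$\widehat m_0$ fit on the pooled internal and external controls;
borrowing enters through the refined fit of $\widehat m_0$.

**Inverse probability of data-source weighting**
(`estimate_tau_ipdw()`): controls are re-weighted to the trial
covariate distribution by
$$\widehat W_i = \frac{(1-A_i)\,\widehat\pi_d(X_i)}
{[1-\widehat\pi_a(X_i)]\,\widehat\pi_d(X_i) + [1-\widehat\pi_d(X_i)]},$$
and $\widehat\mu_{0,ipdw} = n_{rct}^{-1}\sum_i \widehat W_i Y_i$ (a
Hajek-normalized variant is available). At $\pi_d \equiv 1$ the weight
reduces to the familiar within-trial $1/(1-\pi_a)$.

**AIPW** (`estimate_tau_aipw()`) solves the estimating equation of the
efficient influence curve
$$\phi(O) = \frac{1}{q}\Big\{ D[m_1 - m_0 - \tau]
  + \frac{DA}{\pi_a}[Y - m_1] - W^{dr}[Y - m_0] \Big\},
\qquad q = \Pr(D = 1),$$
with the doubly robust control weight
$$W^{dr} = \frac{D(1-A)\pi_d + (1-D)(1-A)\pi_d\, r}
{\pi_d(1-\pi_a) + (1-\pi_d)\, r},$$
where $r(X)$ is the ratio of conditional control-outcome variances
between sources. Two presentation details are worth recording. The
$(1-A)$ factor is applied to both numerator summands: since $D = 0$
implies $A = 0$ the two conventions agree on every observed data point,
and this form gives treated subjects zero control-side weight also in
counterfactual evaluations, keeping the weight internally consistent
with the clever covariate below. And $r$ is modelled as a constant —
fixed at 1 by default (homoscedastic sources), or estimated as the
ratio of mean squared control residuals about $\widehat m_0$
(`estimate_variance_ratio(mode = "pooled_ratio")`, internal over
external, orientation configurable and flagged in the output) — because
no covariate-resolved estimator of this ratio is well established and a
constant keeps $W^{dr}$ stable.

**TMLE** (`estimate_tau_tmle()`) fluctuates the initial outcome fits so
the plug-in solves the same equation. The outcome and fitted
regressions are mapped to $[0,1]$ by $(v - L)/(U - L)$ with
$L = \min Y - \delta$, $U = \max Y + \delta$ ($\delta = 0$ by default: the
sample range is the standard bounding construction for continuous
outcomes), and a one-parameter logistic regression of the scaled
outcome on the clever covariate
$$h(D, A, X) = \frac{1}{\widehat q}\Big\{ \frac{DA}{\widehat\pi_a}
 - \frac{D(1-A)\widehat\pi_d + (1-D)(1-A)\widehat\pi_d\widehat r}
        {\widehat\pi_d(1-\widehat\pi_a) + (1-\widehat\pi_d)\widehat r}
 \Big\}$$
is fit with offset $\mathrm{logit}(\widehat m_A)$. One update suffices:
at the fluctuation MLE the residual part of the influence-curve
equation is the score of this regression, and the leading term is
centered by the plug-in definition of $\widehat\tau_{tmle} =
n_{rct}^{-1}\sum_i D_i[\widehat m_1^*(X_i) - \widehat m_0^*(X_i)]$, so
the equation holds up to the optimizer tolerance (the suite asserts
$|n^{-1}\sum_i \widehat\phi_i| \le 10^{-6}$). As a plug-in, TMLE
respects the outcome bounds at every sample size.

## Nuisance estimation and inference

`fit_nuisances()` fits $\widehat m_1$ on treated subjects,
$\widehat m_0$ on the pooled controls, and $\widehat\pi_d$ on all
subjects, with interchangeable learners (linear/logistic models,
random forests via ranger, or user-supplied fit/predict pairs).
Estimated propensities are truncated to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.01$ by default — a
positivity safeguard for the weights; the truncation threshold and all
truncation events are recorded.

Cross-fitting (default 10 folds) stores out-of-fold predictions for
every subject, so machine-learning nuisances retain valid root-$n$
inference for AIPW and TMLE; folds are a seeded random partition
stratified by $(A, D)$ so every training split contains treated,
internal-control, and external-control units (the stratification scheme
is this package's choice; an unstratified partition can lose a stratum
at these sample sizes). Confidence intervals for the doubly robust
estimators use the closed form
$\widehat\tau \pm z_{1-\alpha/2}\,\mathrm{sd}(\widehat\phi)/\sqrt n$
with the quantile computed from $\alpha$ (1.959964 at $\alpha = .05$),
never a hard-coded 1.96. The singly robust estimators get nonparametric
bootstrap percentile intervals (`bootstrap_ci()`, default $B = 1000$),
resampling within source to preserve the two-sample design — the
bootstrap scheme is a package decision; resamples that lose a required
stratum are redrawn and counted, and the p-value is obtained by
interval inversion.

## Diagnostics and sensitivity analysis

Estimation and assumption assessment travel together:

* `normalized_difference()` — multivariate balance
  $\widehat\Delta_x = \sqrt{2(\bar X_1 - \bar X_0)^\top
  (\widehat\Sigma_1 + \widehat\Sigma_0)^{-1}(\bar X_1 - \bar X_0)}$
  between internal and external control covariates (the comparison
  groups are configurable).
* `propensity_imbalance()` — the difference in average estimated study
  propensity between sources, flagged (never gated) against the 0.25
  reference; hypothesis tests on balance statistics are deliberately
  not provided, since imbalance does not invalidate the estimators — it
  measures the difficulty of the adjustment task.
* `a4_bin_diagnostic()` — controls bucketed by $\widehat\pi_d(x)$ in
  0.05-wide bins; per bin and source the count, mean outcome, and a
  normal 95% interval (bins with one control report no interval rather
  than a t-interval). Systematic within-bin gaps indicate a violation
  of mean exchangeability.
* `estimate_bias_bound()` — the asymptotic bias under a violation
  $u(X) = E[Y|A=0,D=1,X] - E[Y|A=0,D=0,X]$ is
  $E[\Pr(D=0|A=0,X)\,u(X) \mid D=1]$; the function reports its plug-in
  (source-specific regressions for $u$, a logistic model for the
  probability term) together with the factored form
  $\Pr(D=0|A=0)\,E[u(X)|D=1]$. Both are reported without claiming one
  dominates: the factored form is an upper bound only for
  non-adversarial (independent) violation profiles, a sign convention
  the data cannot settle.
* `tipping_point()` — the smallest constant violation magnitude $B$
  that moves the confidence interval to include zero, computed in
  closed form for the location-shift model as the CI bound nearer zero
  divided by $\Pr(D=0|A=0)$ (an iterative search adds nothing for a
  pure shift).

## The synthetic-data generator

Real hybrid-trial datasets of this kind are not redistributable, so the
package ships a generator (`simulate_trial()`) emulating the motivating
design: 150 trial patients randomized 2:1 ($\pi_a = 2/3$), 50 external
controls, and a continuous endpoint. Covariates are two standard
normals and two Bernoulli(0.5); the study propensity is
$\pi_d(x) = \mathrm{expit}(1.3 + 0.7 x_1 + 0.4 x_2 + \alpha_q x_1^2)$ —
non-constant, so treatment and source are dependent and external
controls genuinely differ in covariate distribution from the trial; the
control surface is
$m_0(x) = x^\top(1, 0.8, 0.5, 0.5) + \gamma_1 x_1^2 + \gamma_2 x_1 x_2$
with standard normal noise. The intercept 1.3 makes the marginal trial
fraction roughly match the 150:50 design (exact counts are enforced by
rejection sampling); the slopes produce moderate, realistic imbalance
(a propensity-difference diagnostic around 0.1, well below the 0.25
flag). Under the linear truth $\alpha_q = \gamma = 0$; under the
nonlinear truth $\alpha_q = -0.8$, $\gamma = (0.8, 0.6)$, chosen so
that linear analyst models are *genuinely* misspecified (their
projection error is visible against noise SD 1) while remaining a
surface a random forest can learn at $n = 200$. These values were fixed
once as the package's study conditions.

Analysis settings bind truth and learners: (1) linear truth with
correct linear/logistic models; (2) nonlinear truth, flexible outcome
models but a misspecified linear study propensity; (3) the reverse;
(4) both misspecified; (5) both flexible. In settings 2 and 3 the
singly robust estimator whose nuisance is the flexible one is skipped,
mirroring how such comparison tables are usually reported. Flexible
learners are random forests with ranger's own depth defaults and 200
trees — enough for stable probabilities and conditional means at these
sample sizes while keeping a 1000-replicate study on a single core at
desk scale. The optional `u_shift` parameter lowers external-control
outcomes by a constant, injecting a known violation $u(X) = u_{shift}$
for exercising the diagnostics; `tau_slope` adds effect heterogeneity
in $x_1$ for exploring the distinction between study-population and
pooled effects.

What the generator does *not* emulate: measurement error,
informative missingness (the loader is complete-case by design),
non-normal noise, survival endpoints, and covariate distributions with
the skew and boundedness of real clinical scales. Monte-Carlo results
under this generator therefore demonstrate correctness of the
estimators and the qualitative behavior of the framework — coverage,
type-I error control, efficiency gains from borrowing, double
robustness — not performance guarantees on any particular real trial.

## Numerical choices and degenerate inputs

* Propensity truncation $\varepsilon = 0.01$; the variance-ratio
  estimate is floored at $10^{-3}$.
* TMLE scales with $\delta = 0$ and clamps scaled regressions to
  $[10^{-6}, 1-10^{-6}]$ before the logit; the fluctuation is a
  quasibinomial GLM run to tolerance $10^{-12}$, and non-convergence is
  an error carrying the fluctuation coefficient, never a silent
  fallback. A degenerate outcome ($U = L$) is an error.
* Zero-variance influence values yield a degenerate interval flagged in
  the metadata; an interval equal to a point is reported rather than NA.
* A singular covariance sum in the normalized difference falls back to
  the Moore-Penrose pseudo-inverse with a warning.
* Learners on degenerate strata fail loudly (empty stratum, lost arm in
  a cross-fitting split); a logistic learner facing a constant label
  returns that constant probability.
* Seeds: every stochastic routine takes an explicit seed and restores
  the caller's RNG state, so library calls never perturb user
  randomness; identical (input, seed) pairs are bit-reproducible.

## Problem sizes used by the shipped studies

The replicated studies run by the test suite and the acceptance script
use 1000 replicates for the linear-truth coverage study and 500 for the
random-forest studies — sizes at which binomial Monte-Carlo error
(≈ 0.007 and 0.010 on a coverage proportion) is small against the
effects being measured, while a full run stays in the minutes range on
one core. These are the package's chosen study sizes; scaling
`n_reps` up changes no conclusions, only the Monte-Carlo error.

## Known limitations

* Mean exchangeability is only partially testable; the diagnostics
  support, but can never establish, its validity. The graphical check
  is only as good as the declared causal model.
* The variance-ratio nuisance $r$ is a constant, not
  covariate-resolved; with strongly heteroscedastic sources the
  efficiency (not consistency) of the doubly robust estimators
  suffers.
* Binary outcomes run through the same machinery (the logistic
  fluctuation is natural there), but the simulation engine and the
  shipped studies target the continuous-endpoint design; survival
  outcomes are out of scope.
* Extreme-weight mitigation is limited to truncation; matching on the
  study propensity score is not implemented.
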