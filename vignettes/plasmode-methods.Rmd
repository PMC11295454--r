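---
title: "Methods: plasmode simulation for propensity-score matching estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasmode simulation for propensity-score matching estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package studies

`plasmatch` benchmarks how the choice of propensity-score (PS) estimation
method propagates into treatment-effect estimates under 1:1 caliper matching.
Six estimators of the PS are compared, all fitted on covariate *main effects
only*: maximum-likelihood logistic regression (`PS`), least-squares
multivariate adaptive regression splines (`MARS`), a supervised feed-forward
classifier (`DL`) and a naive variant without regularization (`DL.n`), and an
unsupervised autoencoder whose bottleneck feeds a logistic model (`AE`), plus
an "optimized" variant with the supervised model's regularization block
(`AE.o`). Downstream of each PS the pipeline is identical: greedy 1:1
nearest-neighbour matching without replacement on the logit scale with a
caliper of 0.2 times the SD of the logit PS, a standardized-mean-difference
(SMD) balance check flagging |SMD| > 0.25, and a logistic outcome model on
the matched rows, *doubly adjusted* for the same untransformed main effects.
The estimand is the conditional log odds ratio, so the injected treatment
coefficient of the outcome-generating model is the truth against which bias
and coverage are judged.

A targeted maximum likelihood estimation (TMLE) comparator reuses each
method's PS inside a double-robust estimator of the marginal odds ratio,
with a two-learner super learner (logistic regression and MARS, 5-fold
cross-validation, simplex-constrained NNLS weights) as the initial outcome
model. In simulations TMLE is wired behind the `run_tmle` flag and used as a
cross-check; its home is the single-dataset analysis driver.

# The plasmode design

A plasmode simulation keeps the observed covariate and exposure rows of a
base cohort *unmodified* and simulates only the outcome from a known model,
so covariate correlation structure and exposure-covariate confounding stay
realistic while the truth is controlled.

**Base cohort.** The intended base cohort is a critical-care dataset with
5,735 subjects and 50 mixed-type covariates; `load_cohort()` reads such a
table from CSV. Because that dataset cannot be redistributed, the package
ships a synthetic generator emulating its shape: 22 continuous covariates
(including the nine that the outcome model treats specially: age, PaO2/FiO2
ratio, heart rate, mean blood pressure, Glasgow Coma Score, hematocrit,
sodium, weight, APACHE score), 22 binary and 6 three-level categorical
covariates. The continuous block is multivariate normal with exchangeable
correlation 0.2 — moderate clinical-covariate correlation — and the
binary/categorical covariates are generated through logistic and multinomial
links on that block, so all covariates are mutually dependent. Exposure
follows a logistic model on 12 covariates with slopes
±0.2 × `confounding_strength` and a root-found intercept, giving a
calibratable prevalence (default 0.38, the treated share typical of the
emulated cohort). A base outcome is simulated from a confounded logistic
mechanism with moderate main effects (±0.25–0.3 per SD) and mild versions of
the special nonlinear terms; these are one-time realism choices, not tuning
knobs, and the generator's defaults are the study conditions.

**What the generator does not emulate:** the real cohort's exact marginal
distributions (skewness, heavy tails, spike-at-boundary clinical scores),
its missing-data patterns, and its true 50-covariate coding. Passing tests
on the synthetic cohort therefore validate the *machinery* and the method
ranking under a realistic correlation/confounding structure, not the real
data's numeric results.

**True outcome model.** The outcome model contains main effects of all
covariates, polynomials in age (cubic) and PaO2/FiO2 (quadratic), a
heart-rate × mean-blood-pressure interaction, a three-way Glasgow ×
hematocrit × sodium interaction, exp(weight) and cos(APACHE). Its published
coefficients are not available, so the model is *refit* on the base cohort
with exactly that term list — the standard plasmode construction — after
which the treatment coefficient is overwritten with log(true OR) and the
intercept recalibrated. Calibration happens once per scenario on the base
cohort with exposure strata reweighted to the scenario's exposure
prevalence; this matches the expectation under stratified resampling exactly
(no calibration-stage Monte Carlo error) while keeping one fixed true model
across all replicates.

**Replicates.** Each replicate draws `round(n × prevalence)` treated rows and
the complement of control rows with replacement (exact, deterministic
treated fractions — the design controls prevalence, and exact stratified
counts are the most reproducible way to enforce it), then simulates
`Y ~ Bernoulli(expit(intercept + β_A A + design · β))`. Five scenarios are
pre-registered: the base setting (exposure 30%, outcome 30%, OR 0.7,
n = 3,500), rare exposure (5%), rare outcome (5%), a larger sample
(n = 5,000) and a null effect (OR 1.0); the full study uses 1,000 iterations
per scenario.

# Estimators

**Logistic PS** is plain ML logistic regression on the shared main-effects
design (categoricals reference-coded once, so every estimator sees the same
matrix). Fitted probabilities are clipped to [1e-6, 1 − 1e-6] — the logit
transform downstream needs (0, 1).

**MARS** is fitted by least squares on the binary exposure: a greedy forward
search adds reflected hinge pairs max(0, x − t)/max(0, t − x) (knots at
marginal quantiles, interactions up to order 2, compiled search), and a
backward pass deletes terms, keeping the subset with the best GCV
`(RSS/n)/(1 − enp/n)²`, `enp = m + 3(m−1)/2`. No cross-validation is used.
Least-squares probability predictions can leave (0, 1); they are truncated
and the count reported — this untruncated-scale behaviour is itself one of
the phenomena under study.

**Supervised deep learning** is a sigmoid-output feed-forward classifier
(hidden layers 64–32–16, ReLU) trained with binary cross-entropy and Adam
(learning rate 1e-3, batch 64, 50 epochs by default). The regularization
block — dropout 0.3, L2 penalty 0.01, batch normalization, He normal
initialization — is on for `DL` and entirely off for `DL.n` (which uses
Glorot-uniform initialization, the common unregularized default). The
published architectures behind these labels are not available; the layer
sizes and optimizer here are declared package defaults, all exposed in
`net_config()`.

**Autoencoder** trains encoder 32–16, a *linear* 10-unit bottleneck and a
mirrored decoder with linear output under mean-squared reconstruction loss
(100 epochs by default). How an autoencoder yields a propensity score is not
uniquely defined; this package uses the standard construction of a logistic
regression of exposure on the bottleneck activations. A linear bottleneck
was chosen so the extracted features are not sign-truncated before the
logistic step. `AE.o` switches on the same regularization block as `DL`.

All network training is bit-reproducible given the seed: initialization,
batch shuffling and dropout masks run on a private RNG stream, epochs are
fixed (no early stopping), and prediction uses running batch-norm statistics
with dropout disabled. The engine's analytic gradients, including the
batch-normalization backward pass, are verified against central finite
differences in the test suite.

# Matching, effect estimation, TMLE

Matching is greedy: treated units in data order, each taking the nearest
remaining control on the logit scale within the caliper, ties to the lower
control index. The processing order of the original analyses is unknown;
data order with deterministic tie-breaking was chosen for exact
reproducibility, and the tests prove the greedy output equals an independent
re-implementation on all small instances. Unmatched treated units are
dropped. SMDs divide by the pooled SD of the *pre-matching* sample before
and after matching, so the two columns of the balance table share a
denominator.

The effect estimate is the treatment coefficient of a logistic outcome model
on the matched rows with all main effects as covariates; its SE is the
model-based information-matrix SE (no pair-clustering — the reported "model
SE" of the emulated study is a plain model SE, and the doubly adjusted
conditional log OR is the declared estimand). Replicates with
non-convergence (iteration cap 100, |coefficient| > 15 on standardized
inputs, or a singular information matrix) are excluded listwise per method
and counted; this matters in the rare-exposure scenario, where 175 treated
units meet a 56-column adjustment model.

TMLE follows the two-epsilon fluctuation: clever covariates `H1 = A/g`,
`H0 = −(1−A)/(1−g)` (PS bounded to [0.001, 0.999] inside TMLE only), a
no-intercept logistic fluctuation with offset `logit(Q(A,W))`, targeted
means `ψ1, ψ0`, marginal log OR `logit(ψ1) − logit(ψ0)`, and an
efficient-influence-curve SE with the delta method. The score equations
`mean(H·(Y − Q*)) = 0` are asserted to 1e-6 in the tests, and the saturated
no-covariate case reproduces the closed-form 2×2 log OR.

# Performance measures

Per method and scenario: bias, empirical SE (SD of estimates, n−1
denominator everywhere), MSE, average model SE, coverage, and
bias-eliminated coverage (CIs evaluated at the mean estimate, isolating
variance-estimation error from bias), each with the standard Monte Carlo SE
of simulation-study reporting. "Average model SE" is the arithmetic mean of
reported SEs, following the literal definition in the emulated study; the
root-mean-square-of-variances alternative sits behind `mod_se_rms = TRUE`
because the original wording is ambiguous. The exact identity
`MSE = bias² + empSE²·(n−1)/n` is asserted to 1e-12. Zip-plot data sorts
replicates by |z| = |(estimate − truth)/SE| with fractional centiles
(i − 0.5)/n.

Whether the original study computed its metrics on the log-OR or OR scale is
not stated; this package declares the log-OR scale (the magnitudes of the
published bias/SE values are consistent with it).

# Numerical and scale choices

Intercept calibration solves a monotone scalar equation by `uniroot` to
1e-10. Logistic fits go through `stats::glm.fit` on plain matrices.
Super-learner weights use `pracma::lsqnonneg` normalized to the simplex,
with equal weights as the degenerate fallback and weight 0 for learners
failing any fold. Probability clipping is 1e-6 for PS methods and the
positivity bound 0.001 inside TMLE.

Problem sizes in the shipped tests and acceptance script are desk-scale
choices: the synthetic base cohort keeps the full 5,735 × 50 shape, scenario
runs use 200 replicates (the full 1,000 is one argument away via
`scenario_config()`/`default_scenarios()`), the six-method comparison runs
the networks at 8 epochs with batch 256 (the comparison being qualitative,
reduced epochs trade training polish for replicate count), and the
effect-injection oracle refits the true model on a 150,000-row replicate.
With these sizes a full acceptance run completes in well under an hour on a
single core.

# Known limitations

* The synthetic base cohort is a stand-in; headline numeric results on the
  real cohort (and the published Table-level values) require the real CSV
  via `load_cohort()`.
* The refit outcome model inherits the synthetic base outcome's effect
  sizes; its nonlinear-term coefficients are mild, so the main-effects-only
  misspecification stress is correspondingly mild.
* MARS forward search limits knots to marginal quantiles and 15 basis
  functions by default — a speed/fidelity trade-off; both are configurable.
* The matched-cohort SE ignores pairing, by design (it mirrors the emulated
  analysis); pair-robust variants are out of scope.
* Parallel execution is not built in; runs are deterministic, single-stream.
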