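---
title: "Assessing geographic and temporal stability of a clinical prediction model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing geographic and temporal stability of a clinical prediction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A clinical prediction model developed in one set of hospitals and one time
period is routinely applied in others. Two properties make that defensible:
the baseline risk (the outcome probability of a reference patient) and the
predictor effects (the regression coefficients) should be stable across
centres and across time. `predstab` implements an estimation-based audit of
both, built around a suite of nine logistic regression models with
hospital-level Gaussian random effects, applied here to the setting of an
11-predictor model for 1-year mortality after heart-failure
hospitalisation: patients nested in ~90 hospitals, observed in two study
phases.

The package contains the model suite and its variance-component tests, the
closed-form heterogeneity summaries, a synthetic cohort generator that
reproduces the registry's structure (the original registry data cannot be
redistributed), and a command-line driver (`exec/predstab`).

# The model suite

Throughout, `y` is the binary outcome, `x` the 11 centred predictors, `LP`
the fitted linear predictor of the fixed-effects model (intercept
included), `t` the 0/1 period indicator, and `h` indexes hospitals.

* **Model 1** — plain logistic regression of `y` on `x`. Its fitted `LP`
  is the conventional prediction ignoring place and time.
* **Model 2** — Model 1 plus a hospital random intercept
  `b0_h ~ N(0, sigma^2)`. The fitted intercept `mu` and `sigma` describe
  between-hospital variation in baseline risk.
* **Model 3** — `y ~ LP + (1 | h)`: a recalibration model. Because the
  LP enters uncentred with its intercept, a "reference patient" is one
  with `LP = 0`, the fixed slope estimates the calibration slope (≈ 1 on
  the development data itself), and the fixed intercept is ≈ 0.
* **Model 4** — adds a random slope on `LP` (unstructured 2×2 covariance
  `G`). The likelihood-ratio test against Model 3 on the 2 added
  variance–covariance terms asks whether calibration slopes differ across
  hospitals.
* **Model 5** (one per covariate) — with the LP centred (for numerical
  stability; the offset is recorded), adds a random coefficient for one
  covariate on top of the random intercept and random LP slope (3×3 `G`).
  The df = 3 test removes the covariate's variance and two covariances.
  The covariate's fixed "add-on" effect — its deviation from the effect
  already inside the LP — is reported with its Wald test. A variant keeps
  all 11 covariates as fixed effects (as in Model 2) instead of the
  calibration-slope formulation; both are provided, the calibration form
  being the default.
* **Models 6–8** — temporal analogues: period main effect adjusted for
  the LP (Model 6), period × LP interaction (Model 7), and period × each
  covariate (Model 8; 12 main effects, 11 interactions, per-phase odds
  ratios `exp(beta_j)` and `exp(beta_j + gamma_j)`).
* **Model 9** — the joint model: random intercept, random LP slope,
  random temporal effect and random period × LP interaction (4×4 `G`).
  Three tests follow: the interaction's 4 variance–covariance terms
  (df = 4); then, on the reduced model without the interaction (one fixed
  effect and 4 variance terms removed), the temporal effect's 3 terms
  (df = 3) and the 5 terms involving the LP or the temporal effect
  (df = 5).

A full random-coefficients model in which all 11 predictor effects vary
simultaneously across hospitals (a 12-dimensional `G`, 78 free
variance–covariance parameters) is deliberately refused with an
informative error: it is not reliably estimable at registry scale, and the
one-covariate-at-a-time Model 5 family is the supported alternative.

## Heterogeneity summaries

For a random effect distributed `N(mu, sigma^2)` on the log-odds scale:

* **Median odds ratio**: `MOR = exp(sqrt(2) * sigma * qnorm(0.75))` — the
  median, over random pairs of hospitals, of the odds ratio between the
  higher- and the lower-risk hospital for identical patients. The normal
  quantile is evaluated at full precision (0.674490), not the
  conventional two-sided shorthand 0.6745; the difference is invisible at
  two decimals.
* **Reference-patient probability range**:
  `plogis(mu ± qnorm(0.975) * sigma)` contains the hospital-specific
  outcome probability of a reference patient for the central 95% of
  hospitals (the coverage is configurable).
* **Odds-ratio range**: `exp(mu ± qnorm(0.975) * sigma)` for a covariate
  whose hospital-level coefficients follow that distribution.

All three are closed forms of the *fitted* parameters; reporting rounds
MOR and odds ratios to 2 decimals and probabilities to 3, with full
precision retained in JSON. When the published parameter estimates are
themselves rounded (e.g. a coefficient distribution reported as
N(0.01, sd 0.29)), the ranges implied by the rounded parameters can
differ in the last digit from ranges computed on unrounded estimates;
this package always reports the values implied by the parameters it is
given.

# Estimation

`fit_fixed_logistic()` is a self-contained Newton–Raphson (IRLS)
maximiser of the Bernoulli likelihood with standard errors from the
inverse observed information; separation is flagged when a coefficient
passes 15 on the logit scale while the likelihood still improves, and
rank deficiency is reported with the names of the collinear columns.

`fit_glmm()` maximises the marginal likelihood

    prod_h  ∫ prod_i Bernoulli(y_hi | plogis(x_hi' beta + z_hi' b)) phi(b; 0, G) db

with estimation delegated to `lme4::glmer`: adaptive Gauss–Hermite
quadrature with 15 nodes (configurable) for a single random term, the
Laplace approximation for 2–4 correlated random terms. `G` is
parameterised through its Cholesky factor, so positive semi-definiteness
holds by construction; a variance estimated at the zero boundary is
reported as 0 with a `boundary` flag, not an error. Maximum likelihood
(not REML-style corrections) is used throughout so that log-likelihoods
of nested fits are comparable. Empirical-Bayes hospital effects are the
per-hospital posterior modes at the optimum; their sample SD is always at
most the estimated `sigma` (shrinkage).

## Numerical choices that matter

* **Warm starts.** Models with an uncentred LP and several correlated
  random terms have a local optimum at `sigma_intercept = 0` that traps
  cold-started optimisers. The suite therefore fits each random-effects
  chain bottom-up and starts every higher-dimensional fit from the padded
  Cholesky factor of its nested neighbour, falling back to whichever of
  the warm- and cold-started optima attains the higher likelihood.
* **Matching integration accuracy in tests.** A likelihood-ratio
  statistic formed from a 15-node quadrature fit and a Laplace fit
  absorbs the (small, ~0.01–0.05) quadrature difference into the
  chi-square. For every variance-component test the reduced model is
  therefore refitted at the full model's integration accuracy (Laplace
  vs Laplace); the models *reported* keep their more accurate default
  fits.
* **Degrees of freedom.** The tests deliberately use the naive chi-square
  reference with df equal to the number of variance–covariance terms
  removed (2, 3, 4 or 5), with no boundary mixture correction. At a
  boundary null this over-covers, so the df = 2 calibration-slope test is
  conservative — a property the test suite verifies by simulation.
  Mixture-corrected p-values are intentionally not the default.
* **Clamping.** A nominally negative chi-square within optimizer noise is
  clamped to 0; a deficit beyond 0.5 triggers a warning because it
  indicates an optimisation failure, and the affected test is flagged.
* **Tolerated failures.** Individual Model 5 covariates can fail to fit
  (near-singular 3×3 `G`, rare covariates); failures become notes in the
  suite result rather than aborting the run, and family summaries report
  the minimum and maximum p across the tests that did run, with no
  multiplicity correction (stated in the report footer).

# The synthetic cohort generator

`generate_cohort()` emulates the registry structure the analyses assume:
90 hospitals, 14,857 patients split 7549/7308 across two phases
(patient-level assignment within every hospital, so each hospital is
observed in both phases), hospital random intercepts with SD 0.18 around
a pooled baseline of −1.25 on the log-odds scale, covariate effects equal
to the published random-intercept-model log odds ratios, and a phase-2
log odds ratio of −0.111. Optional heterogeneity sources — a random LP
slope, a random temporal effect, their interaction, and per-covariate
random coefficients — default to zero, so the default cohort is the
"stable prediction model" null with geographic baseline variation only.

Choices the source material does not determine, fixed once here:

* **Covariate marginals.** Only the regression structure, not the
  covariate law, drives the methods, so the continuous predictors are
  independent normals with plausible clinical SDs (age 12 y, SBP
  30 mmHg, respiratory rate 8 /min, serum urea nitrogen 10 units on its
  recorded scale — its published odds ratio is "per unit" with unstated
  units, so the urea scale here is arbitrary and documented as such).
  Binary prevalences (low sodium .15, low hemoglobin .10, cancer .12,
  COPD .20, cerebrovascular disease .15, cirrhosis .01, dementia .10)
  were chosen once, via a logit-normal approximation, so the marginal
  event rate lands near 0.32 with the −1.25 baseline, and then frozen.
* **The baseline is the pooled baseline.** The temporal contrast enters
  the generating log-odds centred at the pooled phase-2 share. A 0/1
  period term would shift the pooled intercept by `gamma * pbar` (≈
  −0.055), so a pooled random-intercept fit would estimate ≈ −1.305
  rather than the intended −1.25. Centring makes `intercept_mu` exactly
  what the pooled Model 2 intercept estimates, while leaving every slope
  (period main effect, interactions) untouched. The period column handed
  to the models remains 0/1.
* **Determinism.** One seed fully determines a cohort; every hospital
  draws from its own seeded substream keyed by hospital index, so
  enlarging `n_clusters` never reshuffles earlier hospitals, and
  replicate seeds derive deterministically from a base seed.

What the generator does **not** emulate: covariate correlations of the
real registry, missing data, non-normal random-effect distributions, and
informative cluster sizes. Passing tests on these cohorts therefore
demonstrates that the machinery recovers known structure of the assumed
form — not that the assumed form fits any particular registry.

# Problem sizes used by the test suite

Module tests run on cohorts of 8–90 hospitals with 30–120 patients each,
chosen so every model (including the 4-dimensional Model 9 chain) is
exercised in seconds. The statistical acceptance checks use: 20
replicates at the full design (90 hospitals × ~165 patients) for
intercept-distribution recovery; one full-size cohort for the
recalibration identity (slope within 0.05 of 1); 50 replicates of 90
hospitals × 50 for the null calibration of the df = 2 test (the bound
`rejection rate ≤ 5%` is a boundary-conservatism property that does not
depend on cluster size); and 10^6 simulated hospital pairs for the
Monte-Carlo check of the MOR closed form.

# Known limitations

* The Laplace approximation for 2–4 random terms is standard but can
  understate variances with very small clusters; single-random-term fits
  use 15-node adaptive quadrature, and the node count is configurable.
* The naive-df tests are faithful to the method being illustrated, not
  optimal; at boundary nulls they are conservative.
* No measure of effect size beyond the variance–covariance terms is
  offered for a significant df = 5 joint test, mirroring the method's own
  limitation.
* Confidence intervals for the MOR itself are not provided.
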