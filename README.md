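# predstab

Geographic and temporal stability of clinical prediction models.

A prediction model that works everywhere and at all times has a stable
baseline risk (intercept) and stable predictor effects (coefficients)
across centres and across periods. `predstab` audits both with a suite of
nine random-effects logistic regression models, applied to the canonical
setting of an 11-predictor model for 1-year mortality after heart-failure
hospitalisation: ~15,000 patients nested in ~90 hospitals observed in two
study phases. It is aimed at biostatisticians validating (or deciding
between) clinical prediction models with multicentre, multi-period data.

## The method in brief

Let `y_hi` be the outcome of patient `i` in hospital `h`, `x` the centred
predictors, `LP` the fitted linear predictor of the plain logistic model
(Model 1), and `t` the period indicator. The suite fits, by maximum
marginal likelihood (adaptive Gauss–Hermite quadrature for one random
term, Laplace for several):

| Model | Structure | Question |
|---|---|---|
| M1 | `logit P(y) = x'β` | reference fit; source of `LP` |
| M2 | `x'β + b0_h` | does baseline risk vary by hospital? |
| M3 | `α + γ·LP + b0_h` | recalibration: hospital-specific baseline for a reference patient |
| M4 | M3 + random slope on `LP` | do calibration slopes vary? (LRT, df = 2) |
| M5 | M4 (LP centred) + random coefficient for one covariate | does one predictor's effect vary? (LRT, df = 3, × 11) |
| M6 | `α + γ·LP + δ·t + b0_h` | did baseline risk shift between periods? |
| M7 | M6 + `t × LP` | did the overall predictor effect shift? |
| M8 | `t`, 11 covariates, 11 `t × x` interactions + `b0_h` | which individual effects shifted? |
| M9 | random intercept, `LP` slope, temporal effect, `t × LP` (4×4 G) | joint geographic–temporal tests (df = 4, 3, 5) |

Between-hospital heterogeneity of a random effect `N(μ, σ²)` is
summarised by the median odds ratio `MOR = exp(√2·σ·Φ⁻¹(0.75))`, the
central-95% range of reference-patient probabilities
`logit⁻¹(μ ± 1.96σ)`, and the central-95% range of hospital-specific odds
ratios `exp(μ ± 1.96σ)`.

Because the original registry data cannot be redistributed, the package
ships a deterministic synthetic cohort generator
(`generate_cohort()`) reproducing the design: 90 hospitals, 14,857
patients split 7549/7308 across two phases, hospital intercepts
`N(−1.25, 0.18²)`, published covariate effects, phase-2 log-OR −0.111.

## Worked example

```r
library(predstab)

cohort <- prepare_cohort(generate_cohort(generator_config(seed = 1L)))
cohort
#> Cohort: 14857 patients, 90 hospitals, periods 7560/7297, 4922 events
#>   predictors: age, sbp, resp_rate, urea, low_sodium, low_hemoglobin, cancer, copd, cvd, cirrhosis, dementia

suite <- run_suite(cohort, models = c("M1", "M2", "M3", "M4", "M6"))
suite
#> Heterogeneity suite: 5 fits, 1 variance-component tests
#>   M1                 logLik    -7645.724  exact
#>   M2                 logLik    -7633.293  quadrature(15)
#>   M3                 logLik    -7633.305  quadrature(15)
#>   M4                 logLik    -7633.010  laplace
#>   M6                 logLik    -7628.873  quadrature(15)
#>   M4_vs_M3               chi2 =   0.634 (df = 2), P = 0.7283
#>   notes: M4: variance estimate at the zero boundary

m2 <- suite$fits$M2
heterogeneity_summary(mu = coef(m2)$estimate[1],
                      sigma = sqrt(m2$G[1, 1]), kind = "intercept")
#> Random intercept ~ N(mu = -1.24, sigma = 0.1839); MOR = 1.19
#>   reference-patient probability in (0.168, 0.293) for 95% of hospitals

pe <- period_effect_summary(suite$fits$M6)
#> Period OR 0.89 (95% CI 0.82-0.96): adjusted odds of the outcome were
#> 11% lower in the second phase
```

Read: baseline mortality of a reference patient varies moderately across
hospitals (for 95% of hospitals the probability lies between 0.168 and
0.293; the median odds ratio between a randomly chosen higher- and
lower-risk hospital is 1.19), calibration slopes do not vary detectably
(P = 0.73 on 2 variance–covariance terms — the generator put no slope
heterogeneity in), and the adjusted odds of death are 11% lower in the
second phase — all of which matches the structure this cohort was
generated with. Model 5's eleven per-covariate tests, the temporal
interaction models and the joint Model 9 run the same way (include
`"M5"`, `"M7"`, `"M8"`, `"M9"` in `models`).

A command-line driver wraps the same functions:

```sh
exec/predstab simulate --out cohort.csv --seed 1
exec/predstab validate --input cohort.csv --out-dir results/
exec/predstab summarize --input fit.json
```

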