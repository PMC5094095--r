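# survpool

Simulation laboratory for a classic question in longitudinal–survival
analysis: when a risk factor is measured repeatedly at scheduled exams, how
much does it matter whether the model accounts for *when* each measurement
was taken? The package is aimed at biostatisticians and epidemiologists
working with exam-cohort data (Framingham-style designs), and at anyone who
needs a seeded, calibrated test bed for time-dependent-covariate
estimators.

## What it implements

**Generator.** Cohorts of `n` subjects with `m` exams at fixed spacing
(default 6 exams, 5 years). Baseline age `A ~ N(35, 5²)`, sex
`S ~ Bern(0.54)`; the longitudinal covariate follows a random
intercept/slope model

    Y_ij = U_i1 + U_i2 · t_ij + τ·A_i + ε_ij,   (U_i1, U_i2) ~ N₂(μ, G),  ε ~ N(0, σ²)

and events come from a proportional-hazards Weibull model with covariates
frozen within intervals,

    h(t) = k λ^k t^(k−1) · exp{α₁·age_j + α₂·S + γ·Y_ij},

drawn interval by interval via the inverse cumulative hazard, with
administrative censoring at the end of follow-up. The scale λ is
*calibrated* to a target cumulative event rate (10%/50%/90%) by seeded
root-finding; γ (the link parameter, a log hazard ratio per unit of Y) is
the estimand.

**Estimators.** Five strategies fit to person-period or counting-process
layouts of the same cohort:

* `CSP_UN` — Cox on pooled within-interval times, unstratified;
* `CSP_AD` — same, stratified by exam interval (time-adjusted);
* `TDCM` — time-dependent Cox on `(start, stop]` counting-process records;
* `PLR_UN` — pooled logistic regression on the event-in-interval indicator;
* `PLR_AD` — pooled logistic with a linear exam-time term.

With common exam times, `CSP_AD` and `TDCM` maximize the same partial
likelihood term by term and return identical estimates and SEs — the
package asserts this to 1e-6.

**Harness.** `run_scenario()` / `run_grid()` run replicated scenarios and
report mean estimate, mean SE, empirical SD, bias, MSE, 95% coverage and
(under the null) Type I error per method and coefficient.

## Worked example

```r
library(survpool)

cfg <- sim_config(n_subjects = 1000, gamma = 0.5, target_event_rate = 0.5,
                  master_seed = 1)
cohort <- simulate_cohort(cfg, replicate_id = 1)
cohort
#> <cohort> replicate 1: 1000 subjects, 6 exams, 531 events (53.1%)

fit_method("TDCM", cohort)
#> <survpool_fit> TDCM (5534 rows, 531 events)
#>      estimate     se  ci_low ci_high p
#> link   0.4738 0.0716  0.3336  0.6141 0
#> age    0.0520 0.0096  0.0332  0.0707 0
#> sex   -0.5442 0.0882 -0.7170 -0.3714 0
```

The cohort was generated with γ = 0.5, α₁ = 0.05, α₂ = −0.5; the
time-dependent Cox fit recovers all three within one standard error. A
small replicated scenario:

```r
res <- run_scenario(scenario_spec(event_rate = 0.5, gamma = 0.5,
                                  n_subjects = 1000, n_replicates = 100,
                                  master_seed = 1))
res
#> <scenario_result> rate 0.5, gamma 0.5, n = 1000, 100 replicates (scale 1.1095e-05)
#>  method mean_estimate mean_se coverage    bias     mse
#>  CSP_UN         0.502  0.0464     0.98 0.00198 0.00158
#>  CSP_AD         0.503  0.0758     0.98 0.00293 0.00479
#>    TDCM         0.503  0.0758     0.98 0.00293 0.00479
#>  PLR_UN         0.544  0.0530     0.95 0.04370 0.00402
#>  PLR_AD         0.569  0.0883     0.91 0.06877 0.01116
```

The Cox-based methods are essentially unbiased; the pooled logistic
methods overestimate the link (odds ratios exceed hazard ratios at a 50%
event rate), a discrepancy that grows sharply at higher event rates and
vanishes as events become rare.

Command-line wrappers live in `scripts/survpool.R`
(`simulate` / `fit` / `run-grid`, YAML-configured, with run manifests);
cohorts round-trip through a documented long-format CSV so the estimators
can also be applied to user data.

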