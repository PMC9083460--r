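# dietmsm

Diet quality and survival after a head-and-neck cancer diagnosis, analyzed
the way the exposure actually behaves: as a time-varying quantity. `dietmsm`
implements a longitudinal nutritional-epidemiology pipeline for cohorts with
annually repeated dietary measurements — six *a priori* diet quality indices
as 5-level time-updated exposures, stabilized inverse-probability weights,
and marginal structural Cox proportional hazards models — together with a
synthetic cohort generator with known causal structure so every stage is
verifiable without access to patient data.

It is aimed at biostatisticians and nutritional epidemiologists analyzing
survivorship cohorts with repeated food-frequency questionnaires, and at
anyone who wants a worked, tested reference implementation of stabilized
IPTW/IPCW weighting for an ordinal exposure.

## The model

For subject *i* with exposure quintile history $\bar A_{it}$, baseline
covariates $V_i$ and time-varying confounders $\bar L_{it}$ (BMI and caloric
intake, which both respond to past diet and predict future diet and
mortality), each person-interval is weighted by

$$sw_{it} = \prod_{k=1}^{t}
\frac{P(A_{ik}=a_{ik}\mid \bar A_{i(k-1)}, V_i)}
     {P(A_{ik}=a_{ik}\mid \bar A_{i(k-1)}, V_i, \bar L_{ik})}
\times
\prod_{k=1}^{t}
\frac{P(C_{ik}=0\mid \bar C_{i(k-1)}, \bar A_{i(k-1)}, V_i)}
     {P(C_{ik}=0\mid \bar C_{i(k-1)}, \bar A_{i(k-1)}, V_i, \bar L_{i(k-1)})},$$

and the marginal structural Cox model

$$\lambda_i(t \mid \bar A_{it}, V_i) = \lambda_0(t)\,
\exp\!\big(\beta_1 A_i(t) + \beta_2 V_i + \beta_3 A_i(t-1)\big)$$

is fit by the weighted partial likelihood with robust variance clustered by
subject. Exposure models are proportional-odds logistic; time-varying
confounders enter the weight denominators through 3-knot restricted cubic
splines; combined weights are truncated at the 98th percentile.
Dose-response is examined with quintile dummies, a quintile-median trend
covariate, SD-scaled linear and quadratic terms, and a 5-knot spline curve
anchored at the median score. See `vignette("methods")` for the full
account.

The six indices: AHEI-2010 (absolute thresholds, 0–110), aMED (median
split, 0–9), DASH (quintile ranks, 8–40), and total/animal-based/plant-based
low-carbohydrate indices (11-stratum macronutrient ranks, 0–30).

## Worked example

Simulate a confounded cohort with a known protective effect
(hazard ratio $e^{-0.2} = 0.82$ per quintile step), weight it, and compare
the marginal structural fit with the unweighted one:

```r
library(dietmsm)

cfg <- sim_config(n_subjects = 5000, seed = 42)
sim <- generate_observational_cohort(cfg)
pp  <- person_periods_from_sim(sim)

w <- compute_stabilized_weights(pp, weight_spec(lag_col = "exposure_lag"))
round(weight_diagnostics(w)[, 2:6], 3)
#>   visit   min   max  mean median
#> 1     1 0.343 2.596 0.995  0.920
#> 2     2 0.261 2.596 0.970  0.877
#> 3     3 0.189 2.596 0.950  0.847

covars <- c("age", "sex", "smoking", "stage", "site")
fit <- fit_msm(pp, w, covariates = covars, lag_col = "exposure_lag")
fit$exposure[, c("term", "hr", "lo", "hi")]
#>   term   hr   lo   hi
#> 1   Q2 0.82 0.62 1.09
#> 2   Q3 0.59 0.42 0.82
#> 3   Q4 0.49 0.33 0.72
#> 4   Q5 0.56 0.38 0.83
```

The weight means sit near 1 (the stabilization diagnostic), and the MSM
quintile hazard ratios track the true gradient 0.82/0.67/0.55/0.45 within
sampling error, while the unweighted fit of the same data is attenuated
toward the null by the confounded feedback (Q5 hazard ratio 0.75 instead of
0.56):

```r
unw <- fit_unweighted(pp, covariates = covars, lag_col = "exposure_lag")
unw$exposure[, c("term", "hr", "lo", "hi")]
#>   term   hr   lo   hi
#> 1   Q2 0.93 0.72 1.20
#> 2   Q3 0.70 0.51 0.95
#> 3   Q4 0.58 0.40 0.83
#> 4   Q5 0.75 0.53 1.06
```

The diet-specific layers work the same way from an intake table:
`build_score_panel` computes all six indices with visit-specific quintiles,
trend values and lags; `apply_exclusions`, `build_timeline`,
`impute_trajectory_mean` and `build_person_periods` turn baseline, visit and
outcome tables into counting-process records; `run_pipeline` chains every
stage over CSV files in a run directory.

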