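---
title: "Methods: diet quality indices, stabilized weights, and marginal structural Cox models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet quality indices, stabilized weights, and marginal structural Cox models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmsm)
```

## The problem

Cohort studies of diet and survival usually enter dietary intake as a
baseline snapshot. When intake is re-measured over follow-up, two things go
wrong with conventional regression. First, a static exposure misclassifies
subjects whose diet changes. Second, adjusting for time-varying covariates
that are themselves affected by past diet — body mass index and caloric
intake are the canonical examples — blocks part of the effect of interest
and can introduce collider bias. This *treatment-confounder feedback* is the
setting marginal structural models (MSMs) were designed for: instead of
conditioning on the time-varying confounders, each person-interval is
weighted by the inverse probability of the exposure and censoring history
actually observed, creating a pseudo-population in which exposure is
unconfounded by the measured history.

`dietmsm` implements this analysis end to end for a head-and-neck cancer
survivorship cohort design: three annual dietary measurements (baseline,
1 year, 2 years post-diagnosis), six *a priori* diet quality indices as the
exposures, all-cause and cancer-specific mortality as outcomes, and
administrative censoring three years after the first study visit.

## Index scoring

Four scoring families are implemented per subject-visit:

* **AHEI-2010** (`score_ahei2010`): eleven components scored 0–10 from
  absolute intake thresholds with linear interpolation between the floor
  and ceiling of each component; total 0–110. The component table
  (`ahei_components()`) ships as an editable configuration because intake
  tables derived from different instruments need different units. Alcohol is
  the one non-monotone component: a moderate window (5–15 g/day) scores 10,
  abstention 2.5, and 42 g/day or more scores 0.
* **aMED** (`score_amed`): nine median-split components scored within the
  visit-specific cohort distribution; the alcohol component is a fixed
  5–15 g/day window regardless of sex; total 0–9.
* **DASH** (`score_dash`): eight components scored 1–5 by within-visit
  quintile rank (reversed for sodium, red/processed meat and
  sugar-sweetened beverages). The sum therefore spans 8–40: the
  operationalization this follows has a floor of 8, although the range is
  often quoted as "0 to 40"; we follow the computable definition.
* **Low-carbohydrate indices** (`score_low_carb`): percent energy from fat
  and protein (total, animal-source or plant-source) scored 0–10 ascending
  across 11 within-visit quantile strata, and carbohydrate scored
  descending; total 0–30. The conventional "decile" label for this index is
  inconsistent with its 0–30 range; eleven strata scored 0–10 reproduce the
  published range and are what we implement.

Quantile machinery is shared and deterministic: tied values are assigned as
a group to the lowest stratum their ranks touch (`assign_quintiles`), so
bin occupancy differs from balance by at most the tie-group size, and a
constant score vector is an error rather than an arbitrary split. Quintiles,
medians and strata are computed within visit; a `baseline_anchored` flag in
`build_score_panel` re-uses the first visit's cutpoints for sensitivity
analyses. The linear-trend covariate assigns each subject the median score
of their quintile at that visit (`trend_values`), and
`transition_summary` computes the 5×5 quintile transition counts between
adjacent visits that alluvial displays visualize.

## Cohort construction

`apply_exclusions` applies the five eligibility filters sequentially
(ineligible tumor site; missing full baseline-FFQ pages; more than 70 blank
FFQ responses; missing baseline covariates; implausible energy above
5,000 kcal/day on any FFQ), counting each subject under the first rule that
removes them, and emits a conservation-checked ledger. FFQ completeness is
represented as boolean flags since raw questionnaire pages are out of scope.

`build_timeline` puts survival time on a days-since-diagnosis scale,
reconstructs missing interior visit dates by adding or subtracting the
cohort median inter-visit gap to the nearest documented date, and applies
administrative censoring three years after the first study visit. Subjects
with only a baseline measurement are censored at the end of the first
interval; subjects missing exactly one of three visits have the missing
visit's index score, caloric intake and BMI replaced by the mean of their
two observed values (`impute_trajectory_mean`, idempotent and flagged).
`build_person_periods` then emits counting-process rows — one per
subject-interval with `(start, stop]` times, interval-updated covariates,
lagged exposure, and event/censoring indicators. Cancer-specific mortality
is handled as a cause-specific hazard: non-cancer deaths censor at the
death time, leaving the time structure identical to the all-cause table.

## Stabilized weights

For a 5-level exposure $A_{ik}$ (the index quintile), baseline covariates
$V_i$ and time-varying confounders $L_{ik}$ (BMI, calories), the stabilized
treatment weight at visit $t$ is

$$sw^{IPTW}_{it} = \prod_{k=1}^{t}
\frac{P(A_{ik} = a_{ik} \mid \bar A_{i(k-1)}, V_i)}
     {P(A_{ik} = a_{ik} \mid \bar A_{i(k-1)}, V_i, \bar L_{ik})},$$

with an analogous censoring weight for remaining uncensored, and the final
weight is their product. Design choices:

* The exposure model family is proportional-odds logistic (`MASS::polr`),
  with multinomial logistic available by configuration; a two-level
  exposure degenerates to binary logistic regression.
* Time-varying confounders enter the denominators through restricted cubic
  splines with three knots at their 10th/50th/90th percentiles
  (`rcs_basis`, a natural cubic spline basis).
* The first interval has no exposure history, so lag terms are dropped
  there and separate first-interval models are fitted.
* In the censoring models the time-varying confounders enter at the
  *preceding* visit by default, mirroring the asymmetry in the weight
  definitions above; `censor_lag_tv = FALSE` switches to current-visit
  values. Administrative censoring at the horizon is non-informative by
  construction and is not modeled; only loss to follow-up is.
* The combined weight is truncated at the 98th percentile of the pooled
  person-period distribution (both raw and truncated values are retained).
  Truncation stabilizes variance at the cost of a small bias, which is why
  the parameter-recovery benchmark below evaluates untruncated weights.

`weight_diagnostics` summarizes min/max/mean/median per index and visit and
flags visits whose mean deviates from 1 by more than 0.5 — with correctly
specified models the stabilized weight means converge to 1.

## Outcome models

`fit_msm` fits the weighted Cox partial likelihood on the counting-process
data with time-updated quintile dummies, the lagged index score, and the
baseline covariates, with robust sandwich variance clustered by subject and
the Efron tie correction; `fit_unweighted` is the same model without
weights and `fit_baseline_cox` is the conventional time-independent model
using baseline exposure only. The lagged exposure term defaults to the
continuous previous-visit score (a lagged-quintile coding is available);
at the first interval, where no previous measurement exists, the current
value is carried back so a single model specification covers all rows.

Dose-response is probed four ways: the quintile-median trend covariate
(`trend_test`), an SD-scaled linear term reported as a hazard ratio per SD
(`continuous_sd_fit`), a Wald test on an added quadratic term, and a
restricted cubic spline with five knots (`rcs_dose_response`) whose curve
is anchored at HR = 1 at the median score with pointwise delta-method
bands. Effect modification by baseline stage, HPV status or tumor site is
assessed by a likelihood-ratio statistic comparing weighted partial
likelihoods with and without score-by-modifier terms
(`interaction_lrt`); this statistic is approximate under weighting, which
is the standard practice it mirrors, and stratum-specific hazard ratios
per SD accompany it. `adjusted_survival_curves` standardizes predicted
survival over the observed (weighted) first-interval covariate
distribution with exposure set to each quintile.
`sensitivity_censor_imputed` re-runs weights and MSM with every
imputed-record subject censored after the first interval.

## The synthetic cohort generator

No public data accompany this design, so the generator is a first-class
module. `generate_observational_cohort` simulates the structure the
analysis assumes: baseline covariates drawn to match the margins of the
cohort design it emulates (age 61 ± 11.4, 24.8% female, 36.3/35.3/28.4%
current/former/never smoking, 69.2% stage III–IV, site
22.6/36.3/41.0% larynx-hypopharynx/oral cavity/oropharynx, BMI 27.7 ± 5.8,
calories log-normal around 2,000 kcal), a 5-level exposure drawn from a
proportional-odds model with linear predictor
$\alpha_{AA}(A_{k-1}-3) + \alpha_{LA} z(L_k)$, confounder feedback
$L_{k+1} = L_k + \gamma_{AL}(A_k-3) + N(0,1)$ (BMI floored at 14), and
per-interval death and dropout. Deaths are cancer-coded with probability
74/93, the cause-of-death split of the emulated design.

The event model uses a complementary-log-log link:
$P(\text{event}) = 1 - \exp\{-\exp(\log H_0 + \beta_A (A_k - 1) +
\alpha_{LY} z(L_k))\}$ with $H_0 = -\log(1 - p_0)$. This is the
discrete-time proportional-hazards formulation, under which $\beta_A$ is
exactly the conditional log hazard ratio per exposure step that the Cox
fits estimate. A logistic link would define $\beta_A$ on the odds scale
and build a systematic scale mismatch of about 0.03 into every recovery
benchmark at these event rates; the cloglog form removes it. Dropout
remains logistic (as do the IPCW models). Generator defaults are
$\alpha_{AA}=0.8$, $\alpha_{LA}=0.6$, $\gamma_{AL}=0.4$,
$\alpha_{LY}=0.3$, $\beta_A=-0.2$, base event probability 0.06 and
dropout probability 0.08 per interval — moderate confounding chosen to
resemble the weight behavior such cohorts exhibit in practice
(per-visit weight means close to 1, ranges well inside [0, 3]).

Two fixtures are deterministic by construction.
`generate_exclusion_fixture` emits 550 subjects with disjoint strata sized
45/17/7/7/6 for the five sequential filters, leaving 468 eligible.
`generate_longitudinal_fixture` emits a 468-subject cohort whose
person-period table has exactly 1,018 rows (179 one-interval, 28
two-interval, 261 three-interval subjects), 93 deaths (74 cancer), and 45
imputable missing-FFQ records (4.4% of rows), 12 of which also lack the
concurrent BMI.

## The parameter-recovery benchmark

`msm_benchmark` is the package's core validation: simulate a confounded
cohort, weight it, and ask whether the MSM recovers the known conditional
effect while the unweighted fit does not. The benchmark regime doubles the
assignment-side feedback parameters ($\alpha_{LA}=1.2$,
$\gamma_{AL}=0.8$) relative to the generator defaults: under the defaults
the unweighted bias is only about 0.08–0.09 on a true effect of −0.2,
which does not separate the estimators cleanly, while the strong-feedback
regime biases the naive estimator by ≈ 0.13–0.14. The
outcome-side effect $\alpha_{LY}$ stays at its default because it governs
the non-collapsibility gap between the conditional parameter and the
marginal quantity an MSM targets; recovery is judged against a tolerance,
not an equality, for exactly this reason.

Three specification details make the benchmark a clean test of the
weighting engine rather than of incidental modeling noise. First, the
weight models use the lagged exposure *level* and current-visit
confounders in the censoring denominators — the generator's true
dependencies (the diet pipeline defaults to the lagged continuous score
and preceding-visit censoring confounders, matching how the analysis
models are written). Second, the weighted outcome model includes the
lagged exposure term: past exposure has a real causal path to the hazard
through the confounder ($\gamma_{AL} \to \alpha_{LY}$), and without the
lagged term the current-exposure coefficient absorbs part of that effect.
The unweighted comparator is deliberately the crude fit with the current
exposure only, because a lagged exposure term is itself a strong proxy
for the confounder and masks roughly half of the bias the weights are
being validated against. Third, the benchmark weights are untruncated:
percentile truncation deliberately trades bias for variance and its
behavior is tested separately. At 200 replicates of n = 5,000 the
replicate-mean MSM estimate sits within 0.02 of the truth with 95% CI
coverage near nominal, while the crude estimate is biased by more
than 0.1.

Problem sizes in the test suite were chosen to make Monte-Carlo error
small relative to the tolerances: n = 5,000 single cohorts for weight-mean
checks, 200 × 5,000 replicates for the recovery benchmark, and
hand-enumerable instances (≤ 30 rows) wherever an exact oracle exists.

## What the generator does and does not emulate

The generator reproduces the *statistical structure* the analysis relies
on — margins, 5-level ordinal exposure with history dependence, confounder
feedback, annual-interval events, informative dropout, administrative
censoring, and the exclusion/imputation bookkeeping. It does not attempt
realistic food-frequency correlation structure between intake components,
nutrient-database derivation, sub-annual covariate dynamics, or
competing-risk dependence between causes of death. Passing tests therefore
demonstrate that the estimators do what they claim under the assumed
structure, not that any particular real-world cohort satisfies that
structure.

## Numerical conventions and limitations

* Quantile binning ties go to the lower bin; percentile truncation uses
  the type-7 sample quantile; spline knots at fixed quantile positions
  (10/50/90 for 3 knots, 5/27.5/50/72.5/95 for 5).
* Ties in event times use the Efron approximation; duplicated datasets are
  therefore invariant only up to the tie correction.
* Positivity violations (zero denominator probability) are errors naming
  the offending row, not silent infinities.
* The weighted likelihood-ratio test for interactions is approximate; the
  robust Wald machinery is exact to first order and is what the headline
  intervals use.
* Competing-risk subdistribution modeling (Fine–Gray), multiple
  imputation, doubly robust estimators and g-computation are out of scope.
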