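Package: dietmsm
Title: Diet Quality Indices and Survival via Marginal Structural Cox Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal nutritional-epidemiology survival analyses
    with time-varying diet exposures. Computes six a priori diet quality
    indices (AHEI-2010, aMED, DASH, and three low-carbohydrate variants) from
    per-visit intake tables, assigns visit-specific quintiles and trend
    covariates, builds counting-process person-period data with trajectory-mean
    imputation and administrative censoring, constructs stabilized inverse
    probability of treatment and censoring weights with restricted cubic spline
    weight models and percentile truncation, and fits marginal structural Cox
    proportional hazards models with robust variance, linear-trend, quadratic,
    spline dose-response and interaction analyses. Includes a synthetic cohort
    generator with known causal structure for validating the weighting engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    nnet,
    splines,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
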