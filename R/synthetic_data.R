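#' Simulation configuration for the observational cohort generator
#'
#' Parameterizes a discrete-time cohort with treatment-confounder feedback:
#' a 5-level ordinal exposure drawn from a proportional-odds model given the
#' previous exposure and the standardized time-varying confounder (BMI), a
#' confounder that responds to past exposure, and per-interval event and
#' dropout probabilities that depend on the current exposure and confounder.
#' With `alpha_LA` and `alpha_LY` both nonzero the unweighted time-varying
#' Cox estimate of the exposure effect is confounded while a correctly
#' weighted marginal structural model is not; this is the benchmark the
#' weighting engine is validated against.
#'
#' @param n_subjects number of subjects.
#' @param n_visits number of annual visits (>= 2; default 3).
#' @param seed integer RNG seed.
#' @param beta_A true conditional log-hazard per one-level exposure step.
#' @param alpha_AA effect of previous exposure (centered at level 3) on the
#'   proportional-odds linear predictor for the next exposure.
#' @param alpha_LA effect of the standardized confounder on exposure
#'   (log-odds per SD).
#' @param gamma_AL effect of current exposure (centered at level 3) on the
#'   next confounder value, in confounder units.
#' @param alpha_LY effect of the standardized confounder on the event
#'   log-hazard.
#' @param base_event_prob per-interval event probability at exposure level 1
#'   and average confounder.
#' @param dropout_prob per-interval loss-to-follow-up probability at average
#'   confounder.
#' @param alpha_Lc effect of the standardized confounder on dropout log-odds.
#' @param cancer_frac probability a death is cancer-related.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects, n_visits = 3, seed = 1,
                       beta_A = -0.2, alpha_AA = 0.8, alpha_LA = 0.6,
                       gamma_AL = 0.4, alpha_LY = 0.3,
                       base_event_prob = 0.06, dropout_prob = 0.08,
                       alpha_Lc = 0.3, cancer_frac = 74 / 93) {
  if (n_subjects < 1) stop("n_subjects must be positive", call. = FALSE)
  if (n_visits < 2) stop("n_visits must be at least 2", call. = FALSE)
  for (p in c(base_event_prob, dropout_prob, cancer_frac))
    if (!is.finite(p) || p <= 0 || p >= 1)
      stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), n_visits = as.integer(n_visits),
    seed = as.integer(seed), beta_A = beta_A, alpha_AA = alpha_AA,
    alpha_LA = alpha_LA, gamma_AL = gamma_AL, alpha_LY = alpha_LY,
    base_event_prob = base_event_prob, dropout_prob = dropout_prob,
    alpha_Lc = alpha_Lc, cancer_frac = cancer_frac
  ), class = "sim_config")
}

# Table-1-style baseline margins used by both the observational generator
# and the fixtures.
draw_baseline <- function(n) {
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = round(stats::rnorm(n, 61, 11.4), 1),
    sex = sample(c("male", "female"), n, TRUE, c(0.752, 0.248)),
    smoking = sample(c("current", "former", "never"), n, TRUE,
                     c(0.363, 0.353, 0.284)),
    education = sample(c("hs_or_less", "more_than_hs"), n, TRUE,
                       c(0.342, 0.658)),
    hpv = sample(c("negative", "positive", "unknown"), n, TRUE,
                 c(0.327, 0.165, 0.509)),
    stage = sample(c("0-II", "III-IV"), n, TRUE, c(0.308, 0.692)),
    ace27 = sample(c("none", "mild", "moderate", "severe"), n, TRUE,
                   c(0.265, 0.485, 0.179, 0.071)),
    treatment = sample(c("surgery", "surgery_adjuvant", "radiation",
                         "chemoradiation", "chemotherapy", "palliative"),
                       n, TRUE, c(0.25, 0.30, 0.10, 0.25, 0.05, 0.05)),
    site = sample(c("larynx_hypopharynx", "oral_cavity", "oropharynx"),
                  n, TRUE, c(0.226, 0.363, 0.410)),
    stringsAsFactors = FALSE
  )
}

# Draw a 5-level ordinal exposure from a proportional-odds model:
# P(A <= j) = expit(c_j - eta) with cutpoints c_j = logit(j/5), so the
# marginal distribution is uniform over 1..5 when eta = 0.
draw_ordinal_exposure <- function(eta) {
  n <- length(eta)
  cuts <- logit((1:4) / 5)
  cdf <- vapply(cuts, function(cj) expit(cj - eta), numeric(n))
  if (n == 1) cdf <- matrix(cdf, nrow = 1)
  u <- stats::runif(n)
  1L + rowSums(u > cdf)
}

#' Generate an observational cohort with known causal structure
#'
#' Simulates the longitudinal structure the analysis assumes: baseline
#' covariates drawn to match the study cohort's margins, a time-varying
#' confounder (BMI) with treatment-confounder feedback, a 5-level exposure,
#' annual-interval deaths and dropout, and an administrative horizon at the
#' end of the last interval. Returns the true conditional exposure effect
#' alongside the data; the truth record is never altered downstream.
#'
#' @param config a [sim_config()].
#' @return list with `baseline`, `visits`, `outcomes` data.frames and
#'   `truth` (list with `beta_A_true`, `confounded`).
#' @export
generate_observational_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be built with sim_config()", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_subjects
  K <- config$n_visits
  baseline <- draw_baseline(n)
  baseline$diagnosis_date <- as.Date("2009-01-01") +
    sample.int(1500, n, TRUE)
  bmi <- pmax(14, stats::rnorm(n, 27.7, 5.8))
  kcal <- stats::rlnorm(n, log(2000), 0.3)
  baseline$bmi0 <- round(bmi, 2)
  baseline$kcal0 <- round(kcal, 1)

  at_risk <- rep(TRUE, n)
  prev_A <- rep(3L, n)
  death_day <- rep(NA_real_, n)
  censor_day <- rep(NA_real_, n)
  horizon <- K * 365
  vis <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(at_risk)
    if (!length(idx)) break
    z <- (bmi[idx] - 27.7) / 5.8
    eta <- config$alpha_AA * (prev_A[idx] - 3) + config$alpha_LA * z
    A <- draw_ordinal_exposure(eta)
    score <- round(50 + 10 * (A - 3) + stats::rnorm(length(idx), 0, 5), 1)
    vis[[k]] <- data.frame(
      subject_id = baseline$subject_id[idx], visit = k,
      visit_date = baseline$diagnosis_date[idx] + (k - 1) * 365,
      exposure = A, score = score,
      bmi = round(bmi[idx], 2), kcal = round(kcal[idx], 1),
      stringsAsFactors = FALSE
    )
    # discrete-time proportional hazards: cloglog link, so beta_A is the
    # conditional log hazard ratio per exposure step that the Cox fits target
    p_evt <- 1 - exp(-exp(log(-log(1 - config$base_event_prob)) +
                            config$beta_A * (A - 1) + config$alpha_LY * z))
    evt <- stats::runif(length(idx)) < p_evt
    death_day[idx[evt]] <- (k - 1) * 365 +
      floor(stats::runif(sum(evt), 30, 360))
    p_cns <- expit(logit(config$dropout_prob) + config$alpha_Lc * z)
    cns <- !evt & stats::runif(length(idx)) < p_cns
    censor_day[idx[cns & k < K]] <- k * 365
    at_risk[idx[evt | cns]] <- FALSE
    keep <- idx[!(evt | cns)]
    prev_A[idx] <- A
    bmi[keep] <- pmax(14, bmi[keep] + config$gamma_AL * (A[!(evt | cns)] - 3) +
                        stats::rnorm(length(keep)))
    kcal[keep] <- kcal[keep] * exp(stats::rnorm(length(keep), 0, 0.1))
  }
  visits <- do.call(rbind, vis)
  visits <- visits[order(visits$subject_id, visits$visit), ]
  rownames(visits) <- NULL

  died <- !is.na(death_day)
  cause <- rep(NA_character_, n)
  cause[died] <- sample(c("cancer", "other"), sum(died), TRUE,
                        c(config$cancer_frac, 1 - config$cancer_frac))
  last_day <- ifelse(died, death_day,
                     ifelse(!is.na(censor_day), censor_day, horizon))
  outcomes <- data.frame(
    subject_id = baseline$subject_id,
    death_date = baseline$diagnosis_date + ifelse(died, death_day, NA),
    cause = cause,
    last_contact_date = baseline$diagnosis_date + last_day,
    stringsAsFactors = FALSE
  )
  truth <- list(beta_A_true = config$beta_A,
                confounded = config$alpha_LA != 0 && config$alpha_LY != 0)
  list(baseline = baseline, visits = visits, outcomes = outcomes,
       truth = truth)
}

#' Person-period table from a simulated cohort
#'
#' Assembles the counting-process rows the weights and model layers consume
#' directly from [generate_observational_cohort()] output: one row per
#' subject-interval with the current exposure, lagged exposure and score,
#' time-varying confounders, baseline covariates, and event/censoring
#' indicators. Loss to follow-up is flagged as `censor_ltfu`; reaching the
#' administrative horizon is not a censoring event.
#'
#' @param sim output of [generate_observational_cohort()].
#' @return data.frame in person-period (counting-process) form.
#' @export
person_periods_from_sim <- function(sim) {
  v <- sim$visits
  b <- sim$baseline
  o <- sim$outcomes
  K <- max(v$visit)
  horizon <- K * 365
  m <- match(v$subject_id, b$subject_id)
  death_day <- as.numeric(o$death_date - b$diagnosis_date)[
    match(v$subject_id, o$subject_id)]
  last_day <- as.numeric(o$last_contact_date - b$diagnosis_date)[
    match(v$subject_id, o$subject_id)]
  start <- (v$visit - 1) * 365
  stop_ <- pmin(v$visit * 365, ifelse(is.na(death_day), Inf, death_day),
                last_day, horizon)
  event <- !is.na(death_day) & death_day <= stop_ & death_day > start
  cancer <- event & o$cause[match(v$subject_id, o$subject_id)] == "cancer"
  censor_ltfu <- !event & last_day <= v$visit * 365 & last_day < horizon
  key_prev <- paste(v$subject_id, v$visit - 1)
  key <- paste(v$subject_id, v$visit)
  mm <- match(key_prev, key)
  pp <- data.frame(
    subject_id = v$subject_id, interval = v$visit,
    start = start, stop = stop_,
    exposure = v$exposure, score = v$score,
    exposure_lag = v$exposure[mm], score_lag = v$score[mm],
    bmi = v$bmi, kcal = v$kcal,
    event = as.integer(event), event_cancer = as.integer(cancer),
    censor_ltfu = as.integer(censor_ltfu),
    b[m, c("age", "sex", "smoking", "education", "hpv", "stage", "ace27",
           "treatment", "site", "bmi0", "kcal0")],
    stringsAsFactors = FALSE
  )
  pp <- pp[pp$stop > pp$start, ]
  rownames(pp) <- NULL
  pp
}

#' Exclusion fixture: a 550-subject roster with flagged exclusion strata
#'
#' Builds the eligibility-screening fixture: 550 subjects with disjoint
#' strata flagged for each sequential exclusion rule (45 with an ineligible
#' tumor site, 17 with missing full baseline-FFQ pages, 7 with more than 70
#' blank responses on one of the three FFQs, 7 with a missing baseline
#' covariate, and 6 otherwise-eligible subjects reporting more than 5,000
#' kcal on at least one FFQ), leaving 468 fully eligible subjects.
#'
#' @param seed integer RNG seed (the packaged fixture uses 42).
#' @return list with `baseline` and `visits` data.frames.
#' @export
generate_exclusion_fixture <- function(seed = 42) {
  set.seed(seed)
  n <- 550
  baseline <- draw_baseline(n)
  baseline$diagnosis_date <- as.Date("2009-06-01") + sample.int(1200, n, TRUE)
  baseline$bmi0 <- round(pmax(14, stats::rnorm(n, 27.7, 5.8)), 2)
  baseline$kcal0 <- round(stats::rlnorm(n, log(2000), 0.25), 1)
  # disjoint strata in the order the filters are applied
  bad_site <- 1:45
  miss_pages <- 46:62
  blank70 <- 63:69
  miss_cov <- 70:76
  high_kcal <- 77:82
  baseline$site[bad_site] <- sample(
    c("nasopharynx", "salivary_gland", "sinonasal"), 45, TRUE)
  baseline$ffq_missing_pages <- seq_len(n) %in% miss_pages
  baseline$ffq_blank_gt70 <- seq_len(n) %in% blank70
  baseline$age[miss_cov[1:4]] <- NA
  baseline$smoking[miss_cov[5:7]] <- NA

  visits <- do.call(rbind, lapply(1:3, function(k) data.frame(
    subject_id = baseline$subject_id, visit = k,
    visit_date = baseline$diagnosis_date + (k - 1) * 365,
    kcal = round(pmin(4800, stats::rlnorm(n, log(2000), 0.25)), 1),
    stringsAsFactors = FALSE
  )))
  over_visit <- sample(1:3, 6, TRUE)
  for (j in seq_along(high_kcal)) {
    row <- visits$visit == over_visit[j] &
      visits$subject_id == baseline$subject_id[high_kcal[j]]
    visits$kcal[row] <- round(stats::runif(1, 5200, 7500), 1)
  }
  visits <- visits[order(visits$subject_id, visits$visit), ]
  rownames(visits) <- NULL
  list(baseline = baseline, visits = visits)
}

#' Intake profile generator for the scoring layer
#'
#' Generates per subject-visit rows with every field the six indices
#' require: food-group servings/day, alcohol, sodium and marine n-3 intake,
#' percent-energy macronutrient fields split by animal/vegetable source,
#' the MUFA:SFA ratio, total energy and BMI. Carbohydrate, protein and fat
#' energy fractions sum to 1 by construction. With
#' `include_extreme = TRUE`, two constructed subjects are appended at every
#' visit: `EXT_HIGH`, maximally adherent on every index, and `EXT_LOW`,
#' maximally non-adherent (these anchor the score-bound tests).
#'
#' @param n number of random subjects (>= 10).
#' @param seed integer RNG seed.
#' @param n_visits number of visits (default 3).
#' @param include_extreme append the constructed extreme subjects.
#' @return data.frame with one row per subject-visit.
#' @export
generate_intake_profiles <- function(n, seed = 1, n_visits = 3,
                                     include_extreme = FALSE) {
  if (n < 10) stop("need at least 10 subjects", call. = FALSE)
  set.seed(seed)
  rows <- list()
  ids <- sprintf("P%04d", seq_len(n))
  for (k in seq_len(n_visits)) {
    g <- function(mean, sd) pmax(0, stats::rnorm(n, mean, sd))
    carb <- stats::rgamma(n, 25, 1)
    prot <- stats::rgamma(n, 8, 1)
    fat <- stats::rgamma(n, 16, 1)
    tot <- carb + prot + fat
    pe_carb <- carb / tot
    pe_prot <- prot / tot
    pe_fat <- fat / tot
    animal_p <- stats::rbeta(n, 6, 3)
    animal_f <- stats::rbeta(n, 6, 3)
    df <- data.frame(
      subject_id = ids, visit = k,
      vegetables = g(2.5, 1.2), fruit = g(1.8, 1), whole_grains = g(1.5, 1),
      nuts_legumes = g(0.8, 0.5), legumes = g(0.4, 0.3), nuts = g(0.5, 0.4),
      red_processed_meat = g(1, 0.6), fish = g(0.4, 0.3), ssb = g(0.7, 0.6),
      lowfat_dairy = g(1, 0.7), cereal = g(1.2, 0.8),
      alcohol_g = pmax(0, stats::rnorm(n, 8, 10)),
      sodium_mg = pmax(500, stats::rnorm(n, 2800, 800)),
      epa_dha_mg = pmax(0, stats::rnorm(n, 120, 90)),
      pct_energy_carb = pe_carb,
      pct_energy_protein_total = pe_prot,
      pct_energy_protein_animal = pe_prot * animal_p,
      pct_energy_protein_veg = pe_prot * (1 - animal_p),
      pct_energy_fat_total = pe_fat,
      pct_energy_fat_animal = pe_fat * animal_f,
      pct_energy_fat_veg = pe_fat * (1 - animal_f),
      pct_energy_pufa = pe_fat * stats::rbeta(n, 3, 10),
      pct_energy_trans = pmax(0.001, stats::rnorm(n, 0.015, 0.007)),
      mufa_sfa_ratio = stats::rlnorm(n, 0, 0.3),
      energy_kcal = stats::rlnorm(n, log(2000), 0.3),
      bmi = pmax(14, stats::rnorm(n, 27.7, 5.8)),
      stringsAsFactors = FALSE
    )
    if (include_extreme) {
      hi <- df[1, ]
      hi$subject_id <- "EXT_HIGH"
      hi[c("vegetables", "fruit", "whole_grains", "nuts_legumes", "legumes",
           "nuts", "fish", "lowfat_dairy", "cereal")] <- 99
      hi[c("red_processed_meat", "ssb")] <- 0
      hi$alcohol_g <- 10
      hi$sodium_mg <- 1
      hi$epa_dha_mg <- 1000
      hi$pct_energy_carb <- 0.01
      hi$pct_energy_protein_total <- 0.40
      hi$pct_energy_protein_animal <- 0.99 * 0.40
      hi$pct_energy_protein_veg <- 0.99 * 0.40
      hi$pct_energy_fat_total <- 0.59
      hi$pct_energy_fat_animal <- 0.99 * 0.59
      hi$pct_energy_fat_veg <- 0.99 * 0.59
      hi$pct_energy_pufa <- 0.15
      hi$pct_energy_trans <- 0
      hi$mufa_sfa_ratio <- 99
      lo <- df[1, ]
      lo$subject_id <- "EXT_LOW"
      lo[c("vegetables", "fruit", "whole_grains", "nuts_legumes", "legumes",
           "nuts", "fish", "lowfat_dairy", "cereal")] <- 0
      lo$red_processed_meat <- 99
      lo$ssb <- 99
      lo$alcohol_g <- 99
      lo$sodium_mg <- 99999
      lo$epa_dha_mg <- 0
      lo$pct_energy_carb <- 0.98
      lo$pct_energy_protein_total <- 0.01
      lo$pct_energy_protein_animal <- 0.001
      lo$pct_energy_protein_veg <- 0.001
      lo$pct_energy_fat_total <- 0.01
      lo$pct_energy_fat_animal <- 0.001
      lo$pct_energy_fat_veg <- 0.001
      lo$pct_energy_pufa <- 0.001
      lo$pct_energy_trans <- 0.08
      lo$mufa_sfa_ratio <- 0.01
      df <- rbind(df, hi, lo)
    }
    rows[[k]] <- df
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$visit), ]
  rownames(out) <- NULL
  out
}

#' Longitudinal accounting fixture (1,018 person-periods, 45 imputable)
#'
#' Builds a deterministic 468-subject cohort whose counting-process table
#' has exactly 1,018 person-periods: 179 subjects contribute one interval,
#' 28 contribute two, and 261 contribute all three. There are 93 deaths (74
#' cancer-related) and 45 subjects with a missing second-visit FFQ (score
#' and caloric intake absent, recoverable by trajectory-mean imputation), 12
#' of whom also lack the second-visit BMI. The imputed share is therefore
#' 45/1018 = 4.4% of records.
#'
#' @param seed integer RNG seed for the continuous filler values (structure
#'   is fixed).
#' @return list with `baseline`, `visits`, `outcomes` data.frames.
#' @export
generate_longitudinal_fixture <- function(seed = 42) {
  set.seed(seed)
  n <- 468
  baseline <- draw_baseline(n)
  baseline$diagnosis_date <- as.Date("2010-01-01") + ((seq_len(n) * 7) %% 600)
  baseline$bmi0 <- round(pmax(14, stats::rnorm(n, 27.7, 5.8)), 2)
  baseline$kcal0 <- round(stats::rlnorm(n, log(2000), 0.25), 1)

  n_visits_of <- rep(c(1L, 2L, 3L), c(179, 28, 261))
  death_interval <- rep(NA_integer_, n)
  death_interval[1:40] <- 1L                 # deaths in interval 1
  death_interval[180:192] <- 2L              # deaths in interval 2
  death_interval[208:247] <- 3L              # deaths in interval 3
  imputable <- 260:304                       # 45 three-visit subjects
  bmi_missing <- 260:271                     # 12 of them lack visit-3 BMI

  rows <- list()
  for (i in seq_len(n)) {
    K <- n_visits_of[i]
    score <- round(stats::rnorm(1, 55, 12) + c(0, stats::rnorm(2, 0, 4)), 1)
    kcal <- round(stats::rlnorm(1, log(2000), 0.2) * exp(c(0,
      stats::rnorm(2, 0, 0.05))), 1)
    bmi <- round(pmax(14, baseline$bmi0[i] + cumsum(c(0,
      stats::rnorm(2, 0, 0.8)))), 2)
    k <- seq_len(K)
    df <- data.frame(
      subject_id = baseline$subject_id[i], visit = k,
      visit_date = baseline$diagnosis_date[i] + (k - 1) * 365,
      score = score[k], kcal = kcal[k], bmi = bmi[k],
      stringsAsFactors = FALSE
    )
    if (i %in% imputable) df[2, c("score", "kcal")] <- NA
    if (i %in% bmi_missing) df[2, "bmi"] <- NA
    rows[[i]] <- df
  }
  visits <- do.call(rbind, rows)
  rownames(visits) <- NULL

  died <- !is.na(death_interval)
  death_date <- as.Date(rep(NA, n))
  death_date[died] <- baseline$diagnosis_date[died] +
    (death_interval[died] - 1) * 365 + 180
  cause <- rep(NA_character_, n)
  cause[which(died)[1:74]] <- "cancer"
  cause[which(died)[75:93]] <- "other"
  last_contact <- baseline$diagnosis_date +
    ifelse(n_visits_of == 3L, 3 * 365, n_visits_of * 365)
  last_contact[died] <- death_date[died]
  outcomes <- data.frame(
    subject_id = baseline$subject_id, death_date = death_date,
    cause = cause, last_contact_date = last_contact,
    stringsAsFactors = FALSE
  )
  list(baseline = baseline, visits = visits, outcomes = outcomes)
}
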