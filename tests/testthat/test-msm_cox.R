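test_that("unit weights reproduce the unweighted fit exactly", {
  pp <- make_sim_pp(400, seed = 13)
  w1 <- fit_msm(pp, rep(1, nrow(pp)), covariates = c("age", "sex"))
  w0 <- fit_unweighted(pp, covariates = c("age", "sex"))
  expect_equal(coef(w1$fit), coef(w0$fit), tolerance = 1e-10)
  expect_equal(w1$n_events, w0$n_events)
  expect_error(fit_msm(pp, rep(-1, nrow(pp))), "positive")
  expect_error(fit_msm(pp, rep(1, 5)), "joined")
})

test_that("Cox coefficients match a grid-search partial likelihood oracle", {
  # one-row-per-subject, untied times, binary exposure
  toy <- data.frame(subject_id = paste0("s", 1:8),
                    time = c(3.1, 5.2, 7.4, 2.6, 8.9, 4.4, 6.1, 9.5),
                    event = c(1, 1, 0, 1, 0, 1, 1, 0),
                    exposure = c(1, 2, 1, 2, 2, 1, 2, 1))
  res <- fit_baseline_cox(toy)
  oracle <- oracle_cox_beta(toy$time, toy$event,
                            as.numeric(toy$exposure == 2))
  expect_equal(unname(coef(res$fit)), oracle, tolerance = 1e-6)

  # counting-process path with a continuous covariate
  pp <- data.frame(subject_id = paste0("s", 1:9), interval = 1, start = 0,
                   stop = c(2.2, 4.7, 1.9, 6.3, 3.3, 8.1, 5.5, 7.7, 9.9),
                   event = c(1, 0, 1, 1, 0, 1, 1, 0, 0),
                   trend_value = c(0.2, 1.4, -0.7, 0.9, 2.2, -1.1, 0.5,
                                   1.8, -0.3))
  tt <- trend_test(pp, NULL, trend_col = "trend_value", lag_col = NULL)
  oracle2 <- oracle_cox_beta(pp$stop, pp$event, pp$trend_value)
  expect_equal(tt$beta, oracle2, tolerance = 1e-6)

  # replicating the dataset preserves the point estimate up to the Efron
  # correction applied to the ties duplication creates
  pp2 <- rbind(pp, transform(pp, subject_id = paste0("t", 1:9)))
  tt2 <- trend_test(pp2, NULL, trend_col = "trend_value", lag_col = NULL)
  expect_equal(tt2$beta, tt$beta, tolerance = 0.05)
})

test_that("no-event and degenerate inputs raise informative errors", {
  toy <- data.frame(subject_id = c("a", "b"), time = c(1, 2),
                    event = c(0, 0), exposure = c(1, 2))
  expect_error(fit_baseline_cox(toy), "no events")
  expect_error(fit_baseline_cox(rbind(toy, toy)), "one row per subject")
  pp <- make_sim_pp(200, seed = 2)
  pp$trend_value <- 5
  expect_error(trend_test(pp, trend_col = "trend_value"), "degenerate")
})

test_that("trend test detects a linear exposure gradient", {
  pp <- make_sim_pp(2000, seed = 23, beta_A = -0.35)
  for (k in sort(unique(pp$interval))) {
    rows <- pp$interval == k
    pp$trend_value[rows] <- trend_values(pp$score[rows], pp$exposure[rows])
  }
  tt <- trend_test(pp, NULL, covariates = "age",
                   trend_col = "trend_value", lag_col = NULL)
  expect_lt(tt$p_trend, 1e-4)
  expect_lt(tt$beta, 0)
})

test_that("continuous SD-scaled fit is scale invariant and detects curvature", {
  pp <- make_sim_pp(1200, seed = 29, beta_A = -0.3)
  f1 <- continuous_sd_fit(pp, NULL, score_col = "score", lag_col = NULL)
  pp10 <- pp
  pp10$score <- pp$score * 10
  f10 <- continuous_sd_fit(pp10, NULL, score_col = "score", lag_col = NULL)
  expect_equal(f1$hr_per_sd, f10$hr_per_sd, tolerance = 1e-8)
  expect_equal(f1$p_quadratic, f10$p_quadratic, tolerance = 1e-6)

  # U-shaped hazard in the standardized score
  set.seed(77)
  ppu <- make_sim_pp(2000, seed = 31, beta_A = 0)
  zc <- (ppu$score - mean(ppu$score)) / sd(ppu$score)
  ppu$event <- rbinom(nrow(ppu), 1, plogis(-2.8 + 0.7 * zc^2))
  fu <- continuous_sd_fit(ppu, NULL, score_col = "score", lag_col = NULL)
  expect_lt(fu$p_quadratic, 0.01)
})

test_that("quadratic Wald test is calibrated under a purely linear effect", {
  set.seed(55)
  rej <- mean(vapply(1:30, function(r) {
    pp <- make_sim_pp(400, seed = 6000 + r, beta_A = -0.3)
    continuous_sd_fit(pp, NULL, score_col = "score",
                      lag_col = NULL)$p_quadratic < 0.05
  }, logical(1)))
  expect_lte(rej, 0.2)
})

test_that("spline dose-response is anchored at the median and shift-invariant", {
  pp <- make_sim_pp(1500, seed = 37, beta_A = -0.4)
  ref <- median(pp$score)
  dr <- rcs_dose_response(pp, NULL, score_col = "score", lag_col = NULL,
                          grid = c(min(pp$score), ref, max(pp$score)))
  expect_equal(dr$hr[dr$score == ref], 1)
  expect_lt(dr$hr[3], dr$hr[1])  # higher score, lower hazard

  shifted <- pp
  shifted$score <- pp$score + 1000
  dr2 <- rcs_dose_response(shifted, NULL, score_col = "score",
                           lag_col = NULL,
                           grid = c(min(pp$score), ref,
                                    max(pp$score)) + 1000)
  expect_equal(dr2$hr, dr$hr, tolerance = 1e-6)
  expect_equal(attr(dr2, "knots"), attr(dr, "knots") + 1000)
  expect_error(rcs_dose_response(pp[1:3, ], NULL, score_col = "score"),
               "too few distinct")
})

test_that("interaction LRT flags stratum-specific effects and rejects bad input", {
  pp <- make_sim_pp(2500, seed = 43, beta_A = 0)
  zc <- (pp$score - mean(pp$score)) / sd(pp$score)
  set.seed(10)
  oro <- pp$site == "oropharynx"
  pp$event <- rbinom(nrow(pp), 1, plogis(-2.9 + 0.8 * zc * oro))
  het <- interaction_lrt(pp, NULL, score_col = "score", modifier = "site",
                         lag_col = NULL)
  expect_lt(het$p_lrt, 0.01)
  expect_equal(nrow(het$stratum_hr), 3)
  expect_gt(het$stratum_hr$hr_per_sd[het$stratum_hr$stratum ==
                                       "oropharynx"], 1)

  hom <- pp
  set.seed(11)
  hom$event <- rbinom(nrow(pp), 1, plogis(-2.9 + 0.4 * zc))
  expect_gt(interaction_lrt(hom, NULL, score_col = "score",
                            modifier = "site", lag_col = NULL)$p_lrt,
            0.001)

  one <- pp
  one$site <- "oral_cavity"
  expect_error(interaction_lrt(one, NULL, score_col = "score",
                               modifier = "site"), "fewer than 2")
})

test_that("adjusted survival curves are monotone and ordered by protection", {
  pp <- make_sim_pp(1500, seed = 47, beta_A = -0.6)
  w <- compute_stabilized_weights(pp, weight_spec(lag_col = "exposure_lag"))
  res <- fit_msm(pp, w, covariates = "age", lag_col = "exposure_lag")
  curves <- adjusted_survival_curves(res, pp, w)
  for (q in unique(curves$quintile)) {
    s <- curves$survival[curves$quintile == q]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  q1 <- curves$survival[curves$quintile == "1"]
  q5 <- curves$survival[curves$quintile == "5"]
  expect_true(all(q5 >= q1 - 1e-12))
})

test_that("cancer-specific fit equals all-cause when every death is cancer", {
  pp <- make_sim_pp(800, seed = 53)
  pp$event_cancer <- pp$event
  a <- fit_unweighted(pp, covariates = "age", outcome = "all_cause",
                      lag_col = NULL)
  c <- fit_unweighted(pp, covariates = "age", outcome = "cancer",
                      lag_col = NULL)
  expect_equal(coef(a$fit), coef(c$fit), tolerance = 1e-12)
})

test_that("imputation sensitivity rerun is a no-op without flags and stable with them", {
  pp <- make_sim_pp(5000, seed = 59)
  pp$imputed <- FALSE
  spec <- weight_spec(lag_col = "exposure_lag")
  none <- sensitivity_censor_imputed(pp, spec)
  expect_equal(coef(none$primary$fit), coef(none$sensitivity$fit),
               tolerance = 1e-10)

  set.seed(61)
  multi <- names(which(table(pp$subject_id) == 3))
  flagged <- sample(multi, round(0.05 * length(multi)))
  pp$imputed <- pp$subject_id %in% flagged & pp$interval == 2
  run <- sensitivity_censor_imputed(pp, spec)
  expect_lt(run$sensitivity$n_person_periods, run$primary$n_person_periods)
  qd <- abs(run$primary$exposure$beta - run$sensitivity$exposure$beta)
  expect_true(all(qd < 0.1))
})
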