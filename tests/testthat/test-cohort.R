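test_that("sequential exclusions reproduce the fixture ledger and conserve counts", {
  fx <- generate_exclusion_fixture(42)
  ex <- apply_exclusions(fx$baseline, fx$visits)
  expect_equal(ex$ledger$n_removed, c(45L, 17L, 7L, 7L, 6L))
  expect_equal(ex$ledger$rule[1], "ineligible_site")
  expect_equal(nrow(ex$baseline), 468)
  expect_equal(nrow(fx$baseline),
               nrow(ex$baseline) + sum(ex$ledger$n_removed))
  expect_true(all(ex$visits$subject_id %in% ex$baseline$subject_id))
})

test_that("exclusions use first-rule precedence and handle edge inputs", {
  b <- data.frame(subject_id = c("a", "b", "c"),
                  site = c("nasopharynx", "oral_cavity", "oropharynx"),
                  age = c(60, NA, 55), sex = "male",
                  stringsAsFactors = FALSE)
  v <- data.frame(subject_id = c("a", "b", "c"), visit = 1,
                  kcal = c(6000, 2000, 2000), stringsAsFactors = FALSE)
  ex <- apply_exclusions(b, v, covariate_cols = c("age", "sex"))
  # subject "a" fails both site and kcal rules but is counted under site
  expect_equal(ex$ledger$n_removed, c(1L, 0L, 0L, 1L, 0L))
  expect_equal(ex$baseline$subject_id, "c")

  empty <- apply_exclusions(b[0, ], v[0, ])
  expect_equal(nrow(empty$baseline), 0)
  expect_equal(sum(empty$ledger$n_removed), 0)

  expect_error(apply_exclusions(rbind(b, b[1, ]), v), "duplicate")
})

test_that("timeline reconstructs missing visit dates via the median gap", {
  dx <- as.Date("2010-01-01")
  baseline <- data.frame(subject_id = c("s1", "s2", "s3"),
                         diagnosis_date = dx, stringsAsFactors = FALSE)
  visits <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 3), visit = rep(1:3, 3),
    visit_date = dx + c(0, 360, 720, 0, 370, 740, 0, NA, 735),
    stringsAsFactors = FALSE)
  outcomes <- data.frame(subject_id = c("s1", "s2", "s3"),
                         death_date = as.Date(NA), cause = NA,
                         last_contact_date = dx + 1200,
                         stringsAsFactors = FALSE)
  tl <- build_timeline(baseline, visits, outcomes)
  # observed adjacent gaps: 360, 360, 370, 370 -> median 365
  expect_equal(tl$subjects$median_gap[1], 365)
  filled <- tl$visit_days$day[tl$visit_days$subject_id == "s3" &
                                tl$visit_days$visit == 2]
  expect_equal(filled, 0 + 365)
  # all three attended everything: censored at the administrative horizon
  expect_equal(tl$subjects$follow_end, rep(3 * 365, 3))
  expect_equal(tl$subjects$event, rep(0L, 3))

  bad <- outcomes
  bad$death_date[1] <- dx - 5
  expect_error(build_timeline(baseline, visits, bad), "before diagnosis")
})

test_that("trajectory-mean imputation is exact, flagged and idempotent", {
  v <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 3), visit = rep(1:3, 3),
    score = c(60, NA, 80, 50, 55, 60, NA, NA, 70),
    kcal = c(1800, NA, 2200, 2000, 2000, 2000, 1500, 1600, 1700),
    stringsAsFactors = FALSE)
  out <- impute_trajectory_mean(v, c("score", "kcal"))
  expect_equal(out$score[out$subject_id == "s1"], c(60, 70, 80))
  expect_equal(out$kcal[out$subject_id == "s1"], c(1800, 2000, 2200))
  expect_equal(out$imputed, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                              FALSE, FALSE, FALSE))
  # two missing visits: left for the censoring rules
  expect_true(all(is.na(out$score[out$subject_id == "s3"][1:2])))
  expect_identical(impute_trajectory_mean(out, c("score", "kcal")), out)
})

test_that("person-period construction places events and censoring correctly", {
  dx <- as.Date("2011-06-01")
  baseline <- data.frame(subject_id = c("e2", "c1"), diagnosis_date = dx,
                         age = 60, stringsAsFactors = FALSE)
  visits <- data.frame(subject_id = c("e2", "e2", "c1"),
                       visit = c(1, 2, 1),
                       visit_date = dx + c(0, 365, 0),
                       score = c(50, 60, 40), stringsAsFactors = FALSE)
  outcomes <- data.frame(
    subject_id = c("e2", "c1"),
    death_date = c(dx + 500, as.Date(NA)),
    cause = c("cancer", NA),
    last_contact_date = c(dx + 500, dx + 200),
    stringsAsFactors = FALSE)
  tl <- build_timeline(baseline, visits, outcomes)
  pp <- build_person_periods(tl, visits, baseline)
  e <- pp[pp$subject_id == "e2", ]
  expect_equal(nrow(e), 2)
  expect_equal(e$event, c(0L, 1L))
  expect_equal(e$stop[2], 500)
  expect_equal(e$event_cancer[2], 1L)
  expect_equal(e$score_lag, c(NA, 50))
  cns <- pp[pp$subject_id == "c1", ]
  expect_equal(nrow(cns), 1)
  expect_equal(cns$censor_ltfu, 1L)
  expect_equal(cns$stop, 200)
})

test_that("longitudinal fixture yields 1,018 person-periods with the designed events", {
  lf <- generate_longitudinal_fixture(42)
  vv <- impute_trajectory_mean(lf$visits)
  expect_equal(sum(vv$imputed), 45)
  tl <- build_timeline(lf$baseline, vv, lf$outcomes)
  pp <- build_person_periods(tl, vv[, setdiff(names(vv), "visit_date")],
                             lf$baseline)
  expect_equal(nrow(pp), 1018)
  expect_equal(sum(pp$event), 93)
  expect_equal(sum(pp$event_cancer), 74)
  # conservation and no leakage past follow-up end
  expect_true(all(tapply(pp$event, pp$subject_id, sum) <= 1))
  expect_true(all(pp$start < pp$stop))
  fe <- tl$subjects$follow_end[match(pp$subject_id,
                                     tl$subjects$subject_id)]
  expect_true(all(pp$stop <= fe))
  expect_equal(nrow(pp),
               sum(table(pp$subject_id)))
  # imputed share matches the fixture design
  expect_equal(round(100 * sum(pp$imputed) / nrow(pp), 1), 4.4)
})
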