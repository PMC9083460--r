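test_that("AHEI-2010 attains its bounds and interpolates component-wise", {
  hi <- make_profile(vegetables = 9, fruit = 6, whole_grains = 8, ssb = 0,
                     nuts_legumes = 2, red_processed_meat = 0,
                     pct_energy_trans = 0.002, epa_dha_mg = 400,
                     pct_energy_pufa = 0.12, sodium_mg = 900,
                     alcohol_g = 10)
  expect_equal(score_ahei2010(hi), 110)
  lo <- make_profile(vegetables = 0, fruit = 0, whole_grains = 0, ssb = 3,
                     nuts_legumes = 0, red_processed_meat = 3,
                     pct_energy_trans = 0.06, epa_dha_mg = 0,
                     pct_energy_pufa = 0.01, sodium_mg = 5000,
                     alcohol_g = 60)
  expect_equal(score_ahei2010(lo), 0)
  # every interpolated component exactly halfway between floor and ceiling
  # scores 5; the alcohol flank at 2.5 g/day scores (2.5 + 10) / 2 = 6.25
  mid <- make_profile()  # defaults are the component midpoints
  expect_equal(score_ahei2010(mid), 10 * 5 + 6.25)
  expect_error(score_ahei2010(mid[, setdiff(names(mid), "sodium_mg")]),
               "sodium_mg")
})

test_that("aMED reproduces a hand-enumerated 4-subject cohort", {
  toy <- do.call(rbind, lapply(1:4, function(i) make_profile(
    subject_id = paste0("s", i),
    vegetables = i, legumes = i, fruit = i, nuts = i, cereal = i,
    fish = i, mufa_sfa_ratio = i,
    red_processed_meat = 5 - i,
    alcohol_g = c(0, 10, 10, 20)[i])))
  # medians are 2.5 for every component: subjects 3,4 beat all 7 good
  # components and the meat cut; alcohol window [5,15] holds for 2,3
  expect_equal(score_amed(toy), c(0L, 1L, 9L, 8L))
  expect_error(score_amed(toy[1, ]), "fewer than 2")
})

test_that("DASH equals brute-force quintile ranks and spans 8-40", {
  set.seed(31)
  prof <- generate_intake_profiles(10, seed = 31)[1:10, ]
  up <- c("fruit", "vegetables", "nuts_legumes", "lowfat_dairy",
          "whole_grains")
  down <- c("sodium_mg", "red_processed_meat", "ssb")
  expected <- Reduce(`+`, c(
    lapply(up, function(f) oracle_ntile(prof[[f]], 5)),
    lapply(down, function(f) 6L - oracle_ntile(prof[[f]], 5))))
  got <- score_dash(prof)
  expect_equal(got, as.integer(expected))
  expect_true(all(got >= 8 & got <= 40))
  expect_error(score_dash(prof[1:4, ]), "at least 5")
})

test_that("low-carbohydrate strata match brute-force 11-quantile binning", {
  prof <- generate_intake_profiles(22, seed = 8)
  prof <- prof[prof$visit == 1, ]
  for (variant in c("total", "animal", "plant")) {
    suffix <- c(total = "total", animal = "animal", plant = "veg")[variant]
    expected <- (oracle_ntile(prof[[paste0("pct_energy_fat_", suffix)]], 11) - 1L) +
      (oracle_ntile(prof[[paste0("pct_energy_protein_", suffix)]], 11) - 1L) +
      (11L - oracle_ntile(prof$pct_energy_carb, 11))
    expect_equal(score_low_carb(prof, variant), as.integer(expected),
                 info = variant)
  }
  expect_error(score_low_carb(prof, "vegan"))
  expect_error(score_low_carb(prof[1:8, ]), "at least 11")
})

test_that("quintile assignment follows the ties-to-lower rule and the oracle", {
  q <- assign_quintiles(1:100)
  expect_equal(q[1:20], rep(1L, 20))
  expect_equal(q[81:100], rep(5L, 20))
  # a 5-way tie straddling the Q2/Q3 boundary collapses into Q2
  scores <- c(1:8, rep(9, 5), 10:21)
  q <- assign_quintiles(scores)
  expect_equal(q[9:13], rep(2L, 5))
  expect_error(assign_quintiles(rep(3, 40)), "degenerate")
  set.seed(99)
  for (n in c(25, 50)) {
    for (r in 1:10) {
      x <- sample(round(rnorm(n, 50, 10)))  # duplicates likely
      if (length(unique(x)) < 2) next
      expect_equal(assign_quintiles(x), oracle_ntile(x, 5))
    }
  }
})

test_that("trend values are within-quintile medians with midpoint ties", {
  scores <- c(10, 12, 14, 10, 20, 7)
  quintiles <- c(1, 1, 1, 2, 2, 3)
  expect_equal(trend_values(scores, quintiles), c(12, 12, 12, 15, 15, 7))
})

test_that("rank-based indices are invariant to monotone transforms, AHEI is not", {
  prof <- generate_intake_profiles(30, seed = 12)
  prof <- prof[prof$visit == 1, ]
  trans <- prof
  rank_fields <- c("vegetables", "legumes", "fruit", "nuts", "cereal",
                   "fish", "mufa_sfa_ratio", "red_processed_meat",
                   "nuts_legumes", "lowfat_dairy", "whole_grains",
                   "sodium_mg", "ssb", "pct_energy_carb",
                   "pct_energy_fat_total", "pct_energy_protein_total")
  for (f in rank_fields) trans[[f]] <- exp(prof[[f]] / max(prof[[f]]))
  expect_equal(score_amed(trans), score_amed(prof))
  expect_equal(score_dash(trans), score_dash(prof))
  expect_equal(score_low_carb(trans), score_low_carb(prof))
  expect_false(isTRUE(all.equal(score_ahei2010(trans),
                                score_ahei2010(prof))))
})

test_that("AHEI-2010 responds monotonically to rewarded and penalized intake", {
  base <- make_profile()
  for (d in c(0.5, 1, 2)) {
    expect_gte(score_ahei2010(make_profile(vegetables = 2.5 + d)),
               score_ahei2010(base))
    expect_lte(score_ahei2010(make_profile(ssb = 0.5 + d)),
               score_ahei2010(base))
    expect_lte(score_ahei2010(make_profile(red_processed_meat = 0.75 + d)),
               score_ahei2010(base))
  }
})

test_that("score panel carries lags and transition summaries conserve subjects", {
  intake <- generate_intake_profiles(15, seed = 4)
  panel <- build_score_panel(intake)
  expect_setequal(unique(panel$index),
                  c("ahei2010", "amed", "dash", "lc_total", "lc_animal",
                    "lc_plant"))
  a <- panel[panel$index == "dash", ]
  v1 <- a[a$visit == 1, ]
  v2 <- a[a$visit == 2, ]
  m <- match(v2$subject_id, v1$subject_id)
  expect_equal(v2$lag_score, v1$score[m])
  expect_true(all(is.na(v1$lag_score)))
  # trend value must sit inside the subject's quintile score range
  for (qq in 1:5) {
    sub <- v1[v1$quintile == qq, ]
    expect_true(all(sub$trend_value >= min(sub$score) &
                      sub$trend_value <= max(sub$score)))
  }

  hand <- data.frame(
    index = "dash",
    subject_id = rep(paste0("s", 1:6), 2),
    visit = rep(1:2, each = 6),
    quintile = c(1, 1, 2, 3, 4, 5, 1, 2, 2, 5, 3, 5),
    score = 0)
  tr <- transition_summary(hand)
  m <- tr$matrices[["dash_v1_v2"]]
  expect_equal(sum(m), 6)
  expect_equal(rowSums(m), c(`1` = 2, `2` = 1, `3` = 1, `4` = 1, `5` = 1))
  expect_equal(m[1, 1], 1)
  expect_equal(m[1, 2], 1)
  expect_equal(m[3, 5], 1)
  expect_equal(m[4, 3], 1)
  lab <- tr$changes$change
  expect_equal(as.integer(table(lab)[c("decrease", "increase",
                                       "no_change")]), c(1L, 2L, 3L))
  same <- hand
  same$quintile <- rep(c(1, 2, 3, 4, 5, 3), 2)
  tr2 <- transition_summary(same)
  expect_true(all(tr2$changes$change == "no_change"))
  expect_equal(sum(diag(tr2$matrices[["dash_v1_v2"]])), 6)
})
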