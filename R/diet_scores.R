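#' @title Diet quality index scoring
#' @description Scoring operations for the six a priori diet quality indices
#'   used in the survival analysis: AHEI-2010 (absolute-threshold), aMED
#'   (median-split), DASH (quintile-rank), and the low-carbohydrate index with
#'   its animal- and plant-based variants (11-stratum macronutrient ranking).
#'   All rank-based indices are computed within a single visit's cohort
#'   distribution; scoring across visits is handled by [build_score_panel()].
#' @name diet_scores
NULL

#' AHEI-2010 component configuration
#'
#' The AHEI-2010 operationalization scores 11 components 0-10 each by
#' absolute intake thresholds with linear interpolation between the floor
#' (score 0) and ceiling (score 10) values, following the Chiuve
#' operationalization. The component table is exposed so thresholds can be
#' inspected or adapted to a differently derived intake table. `floor_value`
#' maps to score 0 and `ceiling_value` to score 10; for penalized components
#' the floor exceeds the ceiling and the interpolation runs downhill. Alcohol
#' is the one non-monotone component: a moderate-intake window
#' (5-15 g/day) scores 10, abstention scores 2.5, and intakes at or beyond
#' 42 g/day score 0, with linear interpolation on either flank.
#'
#' @return data.frame with columns `component`, `field`, `floor_value`,
#'   `ceiling_value`, `type` ("linear" or "window").
#' @export
ahei_components <- function() {
  data.frame(
    component = c("vegetables", "fruit", "whole_grains", "ssb",
                  "nuts_legumes", "red_processed_meat", "trans_fat",
                  "epa_dha", "pufa", "sodium", "alcohol"),
    field = c("vegetables", "fruit", "whole_grains", "ssb", "nuts_legumes",
              "red_processed_meat", "pct_energy_trans", "epa_dha_mg",
              "pct_energy_pufa", "sodium_mg", "alcohol_g"),
    floor_value = c(0, 0, 0, 1, 0, 1.5, 0.04, 0, 0.02, 3337, NA),
    ceiling_value = c(5, 4, 5, 0, 1, 0, 0.005, 250, 0.10, 1112, NA),
    type = c(rep("linear", 10), "window"),
    stringsAsFactors = FALSE
  )
}

# Linear interpolation of one component, clamped to [0, 10]. Works for both
# rewarded (floor < ceiling) and penalized (floor > ceiling) components.
component_linear <- function(x, floor_value, ceiling_value) {
  s <- 10 * (x - floor_value) / (ceiling_value - floor_value)
  pmin(10, pmax(0, s))
}

# Alcohol: 0 g/day -> 2.5; [5, 15] g/day -> 10; >= 42 g/day -> 0;
# linear on (0, 5) and (15, 42).
component_alcohol <- function(g) {
  s <- numeric(length(g))
  s[g <= 0] <- 2.5
  up <- g > 0 & g < 5
  s[up] <- 2.5 + (10 - 2.5) * g[up] / 5
  s[g >= 5 & g <= 15] <- 10
  dn <- g > 15 & g < 42
  s[dn] <- 10 * (42 - g[dn]) / (42 - 15)
  s[g >= 42] <- 0
  s
}

#' Score the AHEI-2010 index
#'
#' Sums 11 components each scored 0-10 from absolute intake thresholds (see
#' [ahei_components()]); the total ranges 0-110. Unlike the other indices
#' this score depends only on the subject's own intake, not on the cohort
#' distribution, so it can be computed row-wise.
#'
#' @param profile data.frame of intake rows (see [generate_intake_profiles()]
#'   for the column dictionary).
#' @param components component threshold table, by default
#'   [ahei_components()].
#' @return numeric vector of scores, one per row of `profile`.
#' @export
score_ahei2010 <- function(profile, components = ahei_components()) {
  for (f in components$field) {
    if (is.null(profile[[f]]))
      stop(sprintf("cannot score AHEI-2010: missing field '%s'", f),
           call. = FALSE)
    if (anyNA(profile[[f]]))
      stop(sprintf("cannot score AHEI-2010: NA in field '%s'", f),
           call. = FALSE)
  }
  total <- numeric(nrow(profile))
  for (i in seq_len(nrow(components))) {
    comp <- components[i, ]
    x <- profile[[comp$field]]
    total <- total + if (comp$type == "window") component_alcohol(x)
      else component_linear(x, comp$floor_value, comp$ceiling_value)
  }
  total
}

#' Score the alternate Mediterranean diet (aMED) index
#'
#' Median-split scoring over one visit's cohort: +1 for intake strictly above
#' the visit-specific cohort median of each beneficial component (vegetables,
#' legumes, fruits, nuts, cereals, fish, MUFA:SFA ratio), +1 for red and
#' processed meat strictly below the median, and +1 for alcohol intake in the
#' 5-15 g/day window. Total 0-9.
#'
#' @param profiles data.frame of intake rows, all from the same visit.
#' @return integer vector of scores 0-9.
#' @export
score_amed <- function(profiles) {
  good <- c("vegetables", "legumes", "fruit", "nuts", "cereal", "fish",
            "mufa_sfa_ratio")
  stopifnot_cols(profiles, c(good, "red_processed_meat", "alcohol_g"),
                 "intake table")
  if (nrow(profiles) < 2)
    stop("aMED medians are degenerate with fewer than 2 subjects",
         call. = FALSE)
  s <- integer(nrow(profiles))
  for (f in good)
    s <- s + (profiles[[f]] > stats::median(profiles[[f]]))
  s <- s + (profiles$red_processed_meat <
              stats::median(profiles$red_processed_meat))
  s <- s + (profiles$alcohol_g >= 5 & profiles$alcohol_g <= 15)
  as.integer(s)
}

#' Score the DASH index
#'
#' Quintile-rank scoring over one visit's cohort across eight food
#' categories. Fruits, vegetables, nuts/legumes, low-fat dairy and whole
#' grains are ranked ascending (top quintile scores 5); sodium, red/processed
#' meat and sugar-sweetened beverages are ranked descending (lowest quintile
#' scores 5). The sum over eight components spans 8-40; the cited
#' operationalization's floor is 8 even though the total is often quoted as
#' "0 to 40".
#'
#' @param profiles data.frame of intake rows, all from the same visit.
#' @return integer vector of scores 8-40.
#' @export
score_dash <- function(profiles) {
  up <- c("fruit", "vegetables", "nuts_legumes", "lowfat_dairy",
          "whole_grains")
  down <- c("sodium_mg", "red_processed_meat", "ssb")
  stopifnot_cols(profiles, c(up, down), "intake table")
  if (nrow(profiles) < 5)
    stop("DASH quintile ranks need at least 5 subjects", call. = FALSE)
  s <- integer(nrow(profiles))
  for (f in up) s <- s + quantile_strata(profiles[[f]], 5)
  for (f in down) s <- s + (6L - quantile_strata(profiles[[f]], 5))
  as.integer(s)
}

#' Score the low-carbohydrate index
#'
#' Ranks percent energy from fat, protein and carbohydrate into 11 cohort
#' quantile strata scored 0-10: ascending for fat and protein, descending for
#' carbohydrate. The `animal` and `plant` variants substitute the
#' animal-source or vegetable-source fat and protein energy fractions. Total
#' 0-30.
#'
#' @param profiles data.frame of intake rows, all from the same visit.
#' @param variant one of "total", "animal", "plant".
#' @return integer vector of scores 0-30.
#' @export
score_low_carb <- function(profiles, variant = c("total", "animal", "plant")) {
  variant <- match.arg(variant)
  suffix <- switch(variant, total = "total", animal = "animal", plant = "veg")
  fat <- paste0("pct_energy_fat_", suffix)
  protein <- paste0("pct_energy_protein_", suffix)
  stopifnot_cols(profiles, c(fat, protein, "pct_energy_carb"), "intake table")
  if (nrow(profiles) < 11)
    stop("low-carbohydrate strata need at least 11 subjects", call. = FALSE)
  s <- (quantile_strata(profiles[[fat]], 11) - 1L) +
    (quantile_strata(profiles[[protein]], 11) - 1L) +
    (11L - quantile_strata(profiles$pct_energy_carb, 11))
  as.integer(s)
}

#' Assign visit-specific quintiles of a score distribution
#'
#' Splits one visit's score vector into quintiles by rank; tied scores are
#' assigned, as a group, to the lower quintile, so bin occupancy can differ by
#' at most the tie-group size. A constant score vector has no quintiles and
#' raises an error.
#'
#' @param scores numeric vector of one visit's index scores.
#' @return integer vector of quintiles 1-5.
#' @export
assign_quintiles <- function(scores) {
  quantile_strata(scores, 5)
}

#' Quintile-median trend covariate
#'
#' Each subject receives the median score of their quintile at that visit;
#' the result is modeled downstream as a continuous time-updated covariate in
#' the linear-trend test.
#'
#' @param scores numeric score vector for one visit.
#' @param quintiles quintile assignment from [assign_quintiles()].
#' @return numeric vector of quintile medians, aligned with `scores`.
#' @export
trend_values <- function(scores, quintiles) {
  med <- tapply(scores, quintiles, stats::median)
  as.numeric(med[as.character(quintiles)])
}

#' Compute the full per-visit score panel
#'
#' Computes all six index scores per subject-visit, assigns visit-specific
#' quintiles and trend values, and carries lagged (previous-visit) score and
#' quintile per subject. The result is long over indices: one row per
#' (subject, visit, index).
#'
#' @param intake intake table with one row per subject-visit (columns
#'   `subject_id`, `visit`, and the intake fields).
#' @param baseline_anchored if TRUE, quintile cutpoints from the first visit
#'   are reused at later visits (sensitivity mode); default is visit-specific
#'   ranking.
#' @return data.frame with columns `subject_id`, `visit`, `index`, `score`,
#'   `quintile`, `trend_value`, `lag_score`, `lag_quintile`.
#' @export
build_score_panel <- function(intake, baseline_anchored = FALSE) {
  stopifnot_cols(intake, c("subject_id", "visit"), "intake table")
  indices <- c("ahei2010", "amed", "dash", "lc_total", "lc_animal", "lc_plant")
  visits <- sort(unique(intake$visit))
  out <- list()
  anchor_breaks <- list()
  for (v in visits) {
    at <- intake[intake$visit == v, , drop = FALSE]
    sc <- data.frame(
      ahei2010 = score_ahei2010(at),
      amed = score_amed(at),
      dash = score_dash(at),
      lc_total = score_low_carb(at, "total"),
      lc_animal = score_low_carb(at, "animal"),
      lc_plant = score_low_carb(at, "plant")
    )
    for (idx in indices) {
      scores <- sc[[idx]]
      if (baseline_anchored && v != visits[1]) {
        br <- anchor_breaks[[idx]]
        q <- as.integer(cut(scores, breaks = br, labels = FALSE,
                            include.lowest = TRUE))
        q[scores <= br[1]] <- 1L
        q[scores >= br[6]] <- 5L
      } else {
        q <- assign_quintiles(scores)
        if (baseline_anchored && v == visits[1]) {
          br <- c(-Inf, vapply(1:4, function(j) max(scores[q == j]),
                               numeric(1)), Inf)
          anchor_breaks[[idx]] <- br
        }
      }
      out[[length(out) + 1]] <- data.frame(
        subject_id = at$subject_id, visit = v, index = idx,
        score = scores, quintile = q,
        trend_value = trend_values(scores, q),
        stringsAsFactors = FALSE
      )
    }
  }
  panel <- do.call(rbind, out)
  panel <- panel[order(panel$index, panel$subject_id, panel$visit), ]
  key_prev <- paste(panel$index, panel$subject_id, panel$visit - 1)
  key <- paste(panel$index, panel$subject_id, panel$visit)
  m <- match(key_prev, key)
  panel$lag_score <- panel$score[m]
  panel$lag_quintile <- panel$quintile[m]
  rownames(panel) <- NULL
  panel
}

#' Quintile transition summary across visits
#'
#' For each index and each pair of adjacent visits, counts the 5x5 matrix of
#' quintile transitions and classifies each subject's move as "increase",
#' "no_change" or "decrease" (the summary underlying alluvial displays of
#' ranking transiency).
#'
#' @param panel output of [build_score_panel()].
#' @return list with `matrices` (named list of 5x5 count matrices, one per
#'   index and visit pair) and `changes` (data.frame of per-subject labels).
#' @export
transition_summary <- function(panel) {
  visits <- sort(unique(panel$visit))
  if (length(visits) < 2)
    stop("transition summary needs at least 2 visits", call. = FALSE)
  matrices <- list()
  changes <- list()
  for (idx in unique(panel$index)) {
    p <- panel[panel$index == idx, ]
    for (j in seq_len(length(visits) - 1)) {
      v1 <- visits[j]; v2 <- visits[j + 1]
      a <- p[p$visit == v1, c("subject_id", "quintile")]
      b <- p[p$visit == v2, c("subject_id", "quintile")]
      mg <- merge(a, b, by = "subject_id", suffixes = c("_from", "_to"))
      tab <- table(factor(mg$quintile_from, levels = 1:5),
                   factor(mg$quintile_to, levels = 1:5))
      matrices[[sprintf("%s_v%d_v%d", idx, v1, v2)]] <- unclass(tab)
      lab <- ifelse(mg$quintile_to > mg$quintile_from, "increase",
                    ifelse(mg$quintile_to < mg$quintile_from, "decrease",
                           "no_change"))
      changes[[length(changes) + 1]] <- data.frame(
        index = idx, subject_id = mg$subject_id, from_visit = v1,
        to_visit = v2, change = lab, stringsAsFactors = FALSE)
    }
  }
  list(matrices = matrices, changes = do.call(rbind, changes))
}
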