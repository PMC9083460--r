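#' Apply the eligibility filters sequentially
#'
#' Removes, in order: (1) tumors in sites outside the eligible head-and-neck
#' set, (2) subjects with missing full baseline-FFQ pages, (3) subjects with
#' more than 70 blank responses on any FFQ, (4) subjects missing a baseline
#' covariate used in the analysis, and (5) subjects reporting more than
#' 5,000 kcal/day on any FFQ. Each subject is counted only under the first
#' rule that removes them; the returned ledger records per-rule removals in
#' application order, so the input count always equals the output count plus
#' the ledger sum.
#'
#' The FFQ completeness flags (`ffq_missing_pages`, `ffq_blank_gt70`) are
#' boolean columns of the baseline table; when absent the corresponding rule
#' removes nobody.
#'
#' @param baseline baseline table (one row per subject).
#' @param visits per-visit table with a `kcal` column.
#' @param eligible_sites character vector of eligible tumor site levels.
#' @param covariate_cols baseline covariate columns checked for missingness.
#' @param kcal_limit implausible-energy threshold (kcal/day).
#' @return list with filtered `baseline`, `visits`, and `ledger` (data.frame
#'   of rule names and removal counts).
#' @export
apply_exclusions <- function(baseline, visits,
                             eligible_sites = c("larynx_hypopharynx",
                                                "oral_cavity", "oropharynx"),
                             covariate_cols = c("age", "sex", "smoking",
                                                "education", "hpv", "stage",
                                                "ace27", "treatment", "site"),
                             kcal_limit = 5000) {
  stopifnot_cols(baseline, c("subject_id", "site"), "baseline table")
  if (anyDuplicated(baseline$subject_id))
    stop("duplicate subject_id in baseline table", call. = FALSE)
  flag_col <- function(col) {
    if (is.null(baseline[[col]])) rep(FALSE, nrow(baseline))
    else baseline[[col]] %in% TRUE
  }
  covariate_cols <- intersect(covariate_cols, names(baseline))
  high_kcal_ids <- if (nrow(visits))
    unique(visits$subject_id[!is.na(visits$kcal) & visits$kcal > kcal_limit])
  else character()

  rules <- list(
    ineligible_site = !(baseline$site %in% eligible_sites),
    missing_ffq_pages = flag_col("ffq_missing_pages"),
    ffq_blank_gt70 = flag_col("ffq_blank_gt70"),
    missing_baseline_covariate =
      rowSums(is.na(baseline[, covariate_cols, drop = FALSE])) > 0,
    kcal_over_limit = baseline$subject_id %in% high_kcal_ids
  )
  keep <- rep(TRUE, nrow(baseline))
  counts <- integer(length(rules))
  for (j in seq_along(rules)) {
    hit <- keep & rules[[j]]
    counts[j] <- sum(hit)
    keep <- keep & !hit
  }
  ledger <- data.frame(rule = names(rules), n_removed = counts,
                       stringsAsFactors = FALSE)
  kept <- baseline[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(baseline = kept,
       visits = visits[visits$subject_id %in% kept$subject_id, ,
                       drop = FALSE],
       ledger = ledger)
}

#' Build the per-subject follow-up timeline
#'
#' Converts dates to days since diagnosis, fills missing interior visit
#' dates by adding or subtracting the cohort median inter-visit gap to the
#' nearest documented date, sets the administrative censoring day 3 years
#' (by default) after each subject's first study visit, and resolves each
#' subject's follow-up end as the earliest of death, loss to follow-up, the
#' end of their last attended interval, and administrative censoring.
#' Subjects with only a baseline visit are censored at the end of the first
#' interval.
#'
#' @param baseline baseline table with `subject_id`, `diagnosis_date`.
#' @param visits per-visit table with `subject_id`, `visit`, `visit_date`.
#' @param outcomes outcome table with `subject_id`, `death_date`, `cause`,
#'   `last_contact_date`.
#' @param horizon_years administrative horizon after the first visit.
#' @return list with `visit_days` (subject, visit, day) and `subjects`
#'   (per-subject event/censoring summary).
#' @export
build_timeline <- function(baseline, visits, outcomes, horizon_years = 3) {
  stopifnot_cols(baseline, c("subject_id", "diagnosis_date"), "baseline")
  stopifnot_cols(visits, c("subject_id", "visit", "visit_date"), "visits")
  stopifnot_cols(outcomes,
                 c("subject_id", "death_date", "last_contact_date"),
                 "outcomes")
  dx <- baseline$diagnosis_date[match(visits$subject_id,
                                      baseline$subject_id)]
  vd <- data.frame(subject_id = visits$subject_id, visit = visits$visit,
                   day = as.numeric(visits$visit_date - dx),
                   stringsAsFactors = FALSE)
  vd <- vd[order(vd$subject_id, vd$visit), ]

  gaps <- unlist(tapply(seq_len(nrow(vd)), vd$subject_id, function(ix) {
    d <- vd$day[ix]; v <- vd$visit[ix]
    diff(d)[diff(v) == 1]
  }))
  median_gap <- stats::median(gaps, na.rm = TRUE)
  if (!is.finite(median_gap)) median_gap <- 365

  # fill missing visit days from the nearest documented adjacent visit
  for (pass in 1:2) {
    for (i in which(is.na(vd$day))) {
      prev <- vd$day[vd$subject_id == vd$subject_id[i] &
                       vd$visit == vd$visit[i] - 1]
      nxt <- vd$day[vd$subject_id == vd$subject_id[i] &
                      vd$visit == vd$visit[i] + 1]
      if (length(prev) == 1 && !is.na(prev)) vd$day[i] <- prev + median_gap
      else if (length(nxt) == 1 && !is.na(nxt)) vd$day[i] <- nxt - median_gap
    }
  }
  if (anyNA(vd$day))
    stop("visit dates could not be reconstructed for some subjects",
         call. = FALSE)

  ids <- baseline$subject_id
  first_day <- vd$day[match(paste(ids, 1), paste(vd$subject_id, vd$visit))]
  admin_day <- first_day + round(horizon_years * 365)
  om <- match(ids, outcomes$subject_id)
  death_day <- as.numeric(outcomes$death_date[om] - baseline$diagnosis_date)
  if (any(!is.na(death_day) & death_day < 0))
    stop("death date before diagnosis date", call. = FALSE)
  last_day <- as.numeric(outcomes$last_contact_date[om] -
                           baseline$diagnosis_date)
  # subjects who attended every scheduled visit are followed to the
  # administrative horizon; early leavers end at the close of their last
  # attended interval
  n_expected <- max(vd$visit)
  last_visit_end <- vapply(ids, function(id) {
    d <- vd$day[vd$subject_id == id]
    if (length(d) >= n_expected) Inf else max(d) + median_gap
  }, numeric(1))
  follow_end <- pmin(admin_day, last_visit_end,
                     ifelse(is.na(last_day), Inf, last_day),
                     ifelse(is.na(death_day), Inf, death_day))
  event <- !is.na(death_day) & death_day <= follow_end
  cause <- if (is.null(outcomes$cause)) rep(NA_character_, length(ids))
           else outcomes$cause[om]
  subjects <- data.frame(
    subject_id = ids, first_day = first_day, admin_day = admin_day,
    follow_end = follow_end, event = as.integer(event),
    cause = cause, median_gap = median_gap, stringsAsFactors = FALSE
  )
  list(visit_days = vd, subjects = subjects)
}

#' Trajectory-mean imputation of a single missing visit
#'
#' Subjects with exactly one missing value among their three visits for a
#' given column have that value replaced by the mean of their two observed
#' measurements; rows touched by imputation are flagged. Subjects missing
#' two or more visits for a column are left untouched (they are handled by
#' the censoring rules instead). The operation is idempotent.
#'
#' @param visits per-visit table.
#' @param value_cols columns to impute (defaults to the diet score, caloric
#'   intake and BMI columns when present).
#' @return `visits` with imputed values and a logical `imputed` column.
#' @export
impute_trajectory_mean <- function(visits,
                                   value_cols = intersect(
                                     c("score", "kcal", "bmi"),
                                     names(visits))) {
  visits <- visits[order(visits$subject_id, visits$visit), ]
  if (is.null(visits$imputed)) visits$imputed <- FALSE
  for (col in value_cols) {
    x <- visits[[col]]
    for (id in unique(visits$subject_id[is.na(x)])) {
      ix <- which(visits$subject_id == id)
      if (length(ix) < 3) next
      miss <- ix[is.na(x[ix])]
      if (length(miss) != 1) next
      visits[[col]][miss] <- mean(x[setdiff(ix, miss)])
      visits$imputed[miss] <- TRUE
    }
  }
  rownames(visits) <- NULL
  visits
}

#' Assemble counting-process person-period records
#'
#' Emits one row per subject-interval with (start, stop] times in days
#' since diagnosis, the interval's covariate values, lagged exposure
#' carried from the previous visit, and event/censoring indicators. Both
#' all-cause and cancer-specific event indicators are emitted; the
#' cancer-specific analysis treats non-cancer deaths as censoring at the
#' death time, which leaves the time structure identical across the two
#' outcomes. Loss to follow-up before the administrative horizon sets
#' `censor_ltfu = 1` on the subject's final row; administrative censoring
#' does not.
#'
#' @param timeline output of [build_timeline()].
#' @param visit_values per-visit covariate table (`subject_id`, `visit`,
#'   plus value columns such as `score`, `exposure`, `quintile`, `bmi`,
#'   `kcal`, `imputed`).
#' @param baseline optional baseline table whose covariate columns are
#'   joined onto every row.
#' @param lag_cols value columns for which a lagged (previous-visit) copy
#'   is emitted as `<col>_lag`.
#' @return person-period data.frame.
#' @export
build_person_periods <- function(timeline, visit_values, baseline = NULL,
                                 lag_cols = intersect(
                                   c("score", "exposure", "quintile"),
                                   names(visit_values))) {
  vd <- timeline$visit_days
  subj <- timeline$subjects
  vv_key <- paste(visit_values$subject_id, visit_values$visit)
  rows <- list()
  for (i in seq_len(nrow(subj))) {
    id <- subj$subject_id[i]
    d <- vd[vd$subject_id == id, ]
    d <- d[order(d$visit), ]
    K <- nrow(d)
    bounds <- c(d$day, max(max(d$day) + 1, subj$admin_day[i]))
    fe <- subj$follow_end[i]
    for (k in seq_len(K)) {
      start <- bounds[k]
      stop_ <- min(bounds[k + 1], fe)
      if (stop_ <= start) break
      is_last <- stop_ >= fe || k == K
      ev <- subj$event[i] == 1 && fe <= stop_ && is_last
      row <- data.frame(subject_id = id, interval = d$visit[k],
                        start = start, stop = stop_,
                        event = as.integer(ev),
                        event_cancer = as.integer(ev &&
                          identical(subj$cause[i], "cancer")),
                        censor_ltfu = as.integer(!ev && is_last &&
                          fe < subj$admin_day[i]),
                        stringsAsFactors = FALSE)
      m <- match(paste(id, d$visit[k]), vv_key)
      ml <- match(paste(id, d$visit[k] - 1), vv_key)
      vcols <- setdiff(names(visit_values),
                       c("subject_id", "visit", "visit_date"))
      for (col in vcols) row[[col]] <- visit_values[[col]][m]
      for (col in lag_cols)
        row[[paste0(col, "_lag")]] <- if (is.na(ml)) NA
          else visit_values[[col]][ml]
      rows[[length(rows) + 1]] <- row
      if (stop_ >= fe) break
    }
  }
  pp <- do.call(rbind, rows)
  if (!is.null(baseline)) {
    bm <- match(pp$subject_id, baseline$subject_id)
    bcols <- setdiff(names(baseline), c("subject_id", "diagnosis_date",
                                        names(pp)))
    for (col in bcols) pp[[col]] <- baseline[[col]][bm]
  }
  if (any(duplicated(paste(pp$subject_id, pp$interval))))
    stop("overlapping intervals in person-period construction",
         call. = FALSE)
  rownames(pp) <- NULL
  pp
}
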