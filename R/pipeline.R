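#' @title Pipeline orchestration
#' @description Stage functions tying the generator, scoring, weighting and
#'   modeling layers into one reproducible file-based pipeline. Each stage
#'   reads and writes CSV under a run directory, validates its input schema,
#'   and can be re-run independently; a given configuration and seed fully
#'   determine every output.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param run_dir directory holding all stage inputs and outputs.
#' @param n_subjects cohort size for the simulate stage.
#' @param seed integer seed governing all randomness.
#' @param indices which diet indices to analyze.
#' @param outcomes which mortality outcomes to fit.
#' @param family exposure weight-model family.
#' @param n_knots_weights spline knots in weight models.
#' @param truncation_percentile weight truncation percentile.
#' @param lag_coding "score" or "quintile" lagged-exposure coding.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(run_dir, n_subjects = 500, seed = 1,
                            indices = c("ahei2010", "amed", "dash",
                                        "lc_total", "lc_animal", "lc_plant"),
                            outcomes = c("all_cause", "cancer"),
                            family = "po", n_knots_weights = 3,
                            truncation_percentile = 98,
                            lag_coding = c("score", "quintile")) {
  lag_coding <- match.arg(lag_coding)
  structure(list(run_dir = run_dir, n_subjects = n_subjects, seed = seed,
                 indices = indices, outcomes = outcomes, family = family,
                 n_knots_weights = n_knots_weights,
                 truncation_percentile = truncation_percentile,
                 lag_coding = lag_coding),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config` returns the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config files", call. = FALSE)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config files", call. = FALSE)
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Generate a diet cohort for the end-to-end pipeline
#'
#' Couples the intake-profile generator with baseline covariates, visit
#' dates and annual-interval outcomes (deaths and dropout drawn at rates
#' matching the study structure but independent of diet — a null cohort for
#' pipeline validation).
#'
#' @param n number of subjects.
#' @param seed integer RNG seed.
#' @param n_visits number of annual visits.
#' @return list with `baseline`, `intake`, `outcomes` data.frames.
#' @export
generate_diet_cohort <- function(n, seed = 1, n_visits = 3) {
  intake <- generate_intake_profiles(n, seed, n_visits)
  set.seed(seed + 1L)
  baseline <- draw_baseline(n)
  baseline$diagnosis_date <- as.Date("2010-01-01") + sample.int(900, n, TRUE)
  first <- intake[intake$visit == 1, ]
  baseline$subject_id <- first$subject_id  # share the intake ids
  baseline$bmi0 <- round(first$bmi, 2)
  baseline$kcal0 <- round(first$energy_kcal, 1)
  intake$visit_date <- baseline$diagnosis_date[
    match(intake$subject_id, baseline$subject_id)] + (intake$visit - 1) * 365

  horizon <- n_visits * 365
  death_day <- rep(NA_real_, n)
  censor_day <- rep(horizon, n)
  for (k in seq_len(n_visits)) {
    alive <- is.na(death_day) & censor_day >= k * 365
    evt <- alive & stats::runif(n) < 0.07
    death_day[evt] <- (k - 1) * 365 + floor(stats::runif(sum(evt), 30, 360))
    drp <- alive & !evt & stats::runif(n) < 0.08
    censor_day[drp] <- k * 365
  }
  died <- !is.na(death_day)
  outcomes <- data.frame(
    subject_id = baseline$subject_id,
    death_date = baseline$diagnosis_date + ifelse(died, death_day, NA),
    cause = ifelse(died, sample(c("cancer", "other"), n, TRUE,
                                c(74 / 93, 19 / 93)), NA),
    last_contact_date = baseline$diagnosis_date +
      ifelse(died, death_day, pmin(censor_day, horizon)),
    stringsAsFactors = FALSE
  )
  # drop intake rows after death/dropout so attendance mirrors follow-up
  last_visit <- pmin(n_visits, ceiling(ifelse(died, death_day,
                                              censor_day) / 365))
  intake <- intake[intake$visit <= last_visit[
    match(intake$subject_id, baseline$subject_id)], ]
  rownames(intake) <- NULL
  list(baseline = baseline, intake = intake, outcomes = outcomes)
}

read_stage_csv <- function(path, cols, what) {
  if (!file.exists(path))
    stop(sprintf("missing upstream output: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, cols, what)
  for (col in intersect(c("visit_date", "diagnosis_date", "death_date",
                          "last_contact_date"), names(df)))
    df[[col]] <- as.Date(df[[col]])
  df
}

log_stage <- function(run_dir, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  cat(line, "\n", file = file.path(run_dir, "pipeline.log"), append = TRUE)
  message(line)
}

#' Simulate stage: write cohort CSVs
#' @param config a [pipeline_config()].
#' @return invisibly, the paths written.
#' @export
pipeline_simulate <- function(config) {
  dir.create(config$run_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- generate_diet_cohort(config$n_subjects, config$seed)
  paths <- file.path(config$run_dir,
                     c("baseline.csv", "intake.csv", "outcomes.csv"))
  utils::write.csv(ch$baseline, paths[1], row.names = FALSE, na = "")
  utils::write.csv(ch$intake, paths[2], row.names = FALSE, na = "")
  utils::write.csv(ch$outcomes, paths[3], row.names = FALSE, na = "")
  log_stage(config$run_dir, "simulate",
            sprintf("n=%d seed=%d rows: baseline=%d intake=%d",
                    config$n_subjects, config$seed, nrow(ch$baseline),
                    nrow(ch$intake)))
  invisible(paths)
}

#' Score stage: compute the six-index score panel and transitions
#' @param config a [pipeline_config()].
#' @return invisibly, the score panel.
#' @export
pipeline_score <- function(config) {
  intake <- read_stage_csv(file.path(config$run_dir, "intake.csv"),
                           c("subject_id", "visit", "vegetables"),
                           "intake table")
  panel <- build_score_panel(intake)
  panel <- panel[panel$index %in% config$indices, ]
  utils::write.csv(panel, file.path(config$run_dir, "scores.csv"),
                   row.names = FALSE, na = "")
  tr <- transition_summary(panel)
  tr_df <- do.call(rbind, lapply(names(tr$matrices), function(nm) {
    m <- tr$matrices[[nm]]
    data.frame(pair = nm, from = rep(1:5, 5), to = rep(1:5, each = 5),
               n = as.vector(m), stringsAsFactors = FALSE)
  }))
  utils::write.csv(tr_df, file.path(config$run_dir, "transitions.csv"),
                   row.names = FALSE)
  log_stage(config$run_dir, "score",
            sprintf("panel rows=%d indices=%d", nrow(panel),
                    length(unique(panel$index))))
  invisible(panel)
}

# Assemble the per-index person-period table from the stage files.
index_person_periods <- function(config, index) {
  rd <- config$run_dir
  baseline <- read_stage_csv(file.path(rd, "baseline.csv"),
                             c("subject_id", "diagnosis_date", "site"),
                             "baseline table")
  intake <- read_stage_csv(file.path(rd, "intake.csv"),
                           c("subject_id", "visit", "energy_kcal", "bmi"),
                           "intake table")
  outcomes <- read_stage_csv(file.path(rd, "outcomes.csv"),
                             c("subject_id", "death_date",
                               "last_contact_date"), "outcome table")
  panel <- read_stage_csv(file.path(rd, "scores.csv"),
                          c("subject_id", "visit", "index", "score",
                            "quintile", "trend_value"), "score panel")
  p <- panel[panel$index == index, ]
  vv <- data.frame(subject_id = p$subject_id, visit = p$visit,
                   score = p$score, exposure = p$quintile,
                   trend_value = p$trend_value, stringsAsFactors = FALSE)
  im <- match(paste(vv$subject_id, vv$visit),
              paste(intake$subject_id, intake$visit))
  vv$kcal <- intake$energy_kcal[im]
  vv$bmi <- intake$bmi[im]
  vv$visit_date <- intake$visit_date[im]
  vv <- impute_trajectory_mean(vv, c("score", "kcal", "bmi"))
  tl <- build_timeline(baseline, vv, outcomes)
  build_person_periods(tl, vv[, setdiff(names(vv), "visit_date")], baseline)
}

#' Weights stage: stabilized weights and diagnostics per index
#' @param config a [pipeline_config()].
#' @return invisibly, the combined weight table.
#' @export
pipeline_weights <- function(config) {
  spec <- weight_spec(
    lag_col = paste0(if (config$lag_coding == "score") "score" else
      "exposure", "_lag"),
    baseline_covars = c("age", "sex", "smoking", "stage", "site"),
    n_knots = config$n_knots_weights,
    truncation_percentile = config$truncation_percentile,
    family = config$family)
  all_w <- list()
  for (index in config$indices) {
    pp <- index_person_periods(config, index)
    w <- compute_stabilized_weights(pp, spec)
    w$index <- index
    all_w[[index]] <- w
  }
  weights <- do.call(rbind, all_w)
  rownames(weights) <- NULL
  utils::write.csv(weights, file.path(config$run_dir, "weights.csv"),
                   row.names = FALSE)
  diag <- weight_diagnostics(weights)
  utils::write.csv(diag, file.path(config$run_dir,
                                   "weight_diagnostics.csv"),
                   row.names = FALSE)
  log_stage(config$run_dir, "weights",
            sprintf("rows=%d mean sw=%.3f", nrow(weights),
                    mean(weights$sw)))
  invisible(weights)
}

#' Fit stage: the three model classes plus trend/continuous/spline results
#' @param config a [pipeline_config()].
#' @return invisibly, the results table.
#' @export
pipeline_fit <- function(config) {
  rd <- config$run_dir
  weights <- read_stage_csv(file.path(rd, "weights.csv"),
                            c("subject_id", "interval", "sw", "index"),
                            "weight table")
  covars <- c("age", "sex", "smoking", "education", "hpv", "stage",
              "ace27", "treatment", "site", "bmi0", "kcal0")
  lag_col <- if (config$lag_coding == "score") "score_lag" else
    "exposure_lag"
  rows <- list()
  curves <- list()
  for (index in config$indices) {
    pp <- index_person_periods(config, index)
    wm <- match(paste(pp$subject_id, pp$interval),
                paste(weights$subject_id[weights$index == index],
                      weights$interval[weights$index == index]))
    sw <- weights$sw[weights$index == index][wm]
    for (outcome in config$outcomes) {
      msm <- fit_msm(pp, sw, covars, outcome, lag_col = lag_col)
      unw <- fit_unweighted(pp, covars, outcome, lag_col = lag_col)
      bl <- pp[pp$interval == 1, ]
      bl$time <- tapply(pp$stop, pp$subject_id, max)[bl$subject_id]
      ev <- event_column(outcome)
      bl[[ev]] <- tapply(pp[[ev]], pp$subject_id, max)[bl$subject_id]
      base <- fit_baseline_cox(bl, covars, outcome)
      for (res in list(msm, unw, base)) {
        tt <- if (res$model_type == "baseline")
          trend_test(transform(bl, start = 0, stop = time), NULL, covars,
                     outcome, lag_col = NULL) else
          trend_test(pp, if (res$model_type == "msm") sw, covars, outcome,
                     lag_col = lag_col)
        cs <- if (res$model_type == "baseline") NULL else
          continuous_sd_fit(pp, if (res$model_type == "msm") sw, covars,
                            outcome, lag_col = lag_col)
        hr <- res$exposure
        rows[[length(rows) + 1]] <- data.frame(
          index = index, outcome = outcome, model = res$model_type,
          t(stats::setNames(sprintf("%.2f (%.2f-%.2f)", hr$hr, hr$lo,
                                    hr$hi), paste0("Q", 2:5))),
          p_trend = tt$p_trend,
          p_q5_q1 = res$p_q5_q1,
          hr_continuous = if (is.null(cs)) NA else cs$hr_per_sd,
          p_quadratic = if (is.null(cs)) NA else cs$p_quadratic,
          n_events = res$n_events, stringsAsFactors = FALSE)
      }
      dr <- rcs_dose_response(pp, sw, covars, outcome, lag_col = lag_col)
      curves[[length(curves) + 1]] <- data.frame(index = index,
                                                 outcome = outcome, dr)
    }
  }
  results <- do.call(rbind, rows)
  utils::write.csv(results, file.path(rd, "model_results.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, curves),
                   file.path(rd, "dose_response_curves.csv"),
                   row.names = FALSE)
  log_stage(rd, "fit", sprintf("results rows=%d", nrow(results)))
  invisible(results)
}

#' Report stage: plain-text run summary
#' @param run_dir the run directory.
#' @return invisibly, the report path.
#' @export
pipeline_report <- function(run_dir) {
  res_path <- file.path(run_dir, "model_results.csv")
  if (!file.exists(res_path))
    stop("no fit outputs found in run directory; run pipeline_fit first",
         call. = FALSE)
  res <- utils::read.csv(res_path, stringsAsFactors = FALSE)
  diag <- utils::read.csv(file.path(run_dir, "weight_diagnostics.csv"),
                          stringsAsFactors = FALSE)
  path <- file.path(run_dir, "report.txt")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("Diet-quality MSM survival analysis: run summary", ""), con)
  writeLines("== Stabilized weight diagnostics (per index and visit) ==",
             con)
  utils::capture.output(print(diag, digits = 3), file = con)
  writeLines(c("", "== Model comparison (MSM vs unweighted vs baseline) =="),
             con)
  utils::capture.output(print(res, digits = 3), file = con)
  invisible(path)
}

#' Run every pipeline stage in order
#' @param config a [pipeline_config()].
#' @return invisibly, the run directory.
#' @export
run_pipeline <- function(config) {
  pipeline_simulate(config)
  pipeline_score(config)
  pipeline_weights(config)
  pipeline_fit(config)
  pipeline_report(config$run_dir)
  invisible(config$run_dir)
}
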