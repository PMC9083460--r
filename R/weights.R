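#' Weight model specification
#'
#' Bundles the choices that define the stabilized-weight models: the
#' exposure model family for the 5-level treatment (proportional-odds
#' logistic by default, multinomial optionally), the baseline covariates
#' shared by numerator and denominator, the time-varying confounders that
#' enter only the denominator through restricted cubic spline bases (3 knots
#' at the 10th/50th/90th percentiles by default), the lag coding for the
#' previous-visit exposure, and the truncation percentile of the combined
#' stabilized weight. In the censoring models the time-varying confounders
#' enter at the preceding visit (`censor_lag_tv = TRUE`); a switch allows
#' current-visit values instead.
#'
#' @param exposure_col column holding the 5-level exposure.
#' @param lag_col column holding the lagged exposure term used in both
#'   numerator and denominator (continuous lagged score by default).
#' @param baseline_covars character vector of baseline covariate columns.
#' @param tv_covars time-varying confounder columns (denominator only).
#' @param n_knots knots for the restricted cubic spline bases.
#' @param truncation_percentile percentile at which the combined weight is
#'   truncated (98 by default; 100 disables truncation).
#' @param family "po" (proportional odds) or "multinomial".
#' @param censor_lag_tv use preceding-visit confounder values in the
#'   censoring denominator.
#' @return list of class `weight_spec`.
#' @export
weight_spec <- function(exposure_col = "exposure", lag_col = "score_lag",
                        baseline_covars = character(),
                        tv_covars = c("bmi", "kcal"), n_knots = 3,
                        truncation_percentile = 98,
                        family = c("po", "multinomial"),
                        censor_lag_tv = TRUE) {
  family <- match.arg(family)
  if (n_knots < 3) stop("spline bases need at least 3 knots", call. = FALSE)
  if (truncation_percentile <= 0 || truncation_percentile > 100)
    stop("truncation percentile must lie in (0, 100]", call. = FALSE)
  structure(list(exposure_col = exposure_col, lag_col = lag_col,
                 baseline_covars = baseline_covars, tv_covars = tv_covars,
                 n_knots = n_knots,
                 truncation_percentile = truncation_percentile,
                 family = family, censor_lag_tv = censor_lag_tv),
            class = "weight_spec")
}

# Append restricted cubic spline basis columns for each covariate in `cols`
# (knots from the pooled person-period distribution); returns the augmented
# data and the names of the new columns.
add_spline_columns <- function(pp, cols, n_knots, prefix = "") {
  new_cols <- character()
  for (col in cols) {
    b <- rcs_basis(pp[[col]], n_knots)
    cn <- paste0(prefix, col, "_rcs", seq_len(ncol(b)))
    for (j in seq_len(ncol(b))) pp[[cn[j]]] <- b[, j]
    new_cols <- c(new_cols, cn)
  }
  list(pp = pp, cols = new_cols)
}

fit_categorical <- function(formula, data, family) {
  y <- stats::model.frame(formula, data)[[1]]
  if (length(unique(y)) < 2)
    stop("degenerate exposure distribution: fewer than 2 observed levels",
         call. = FALSE)
  if (nlevels(y) == 2) {
    # a 2-level ordinal/multinomial model is binary logistic regression
    lev <- levels(y)
    f2 <- stats::update(formula, stats::as.formula(
      sprintf("I(%s == '%s') ~ .", all.vars(formula)[1], lev[2])))
    fit <- stats::glm(f2, data = data, family = stats::binomial())
    return(structure(list(fit = fit, levels = lev),
                     class = "binary_exposure_fit"))
  }
  if (family == "po") {
    fit <- tryCatch(
      MASS::polr(formula, data = data, method = "logistic", Hess = FALSE),
      error = function(e) stop("exposure model failed to fit: ",
                               conditionMessage(e), call. = FALSE))
  } else {
    fit <- nnet::multinom(formula, data = data, trace = FALSE,
                          maxit = 300, MaxNWts = 5000)
  }
  fit
}

prob_observed <- function(fit, data, observed) {
  if (inherits(fit, "binary_exposure_fit")) {
    p2 <- stats::predict(fit$fit, newdata = data, type = "response")
    out <- ifelse(as.character(observed) == fit$levels[2], p2, 1 - p2)
    return(as.numeric(out))
  }
  p <- stats::predict(fit, newdata = data, type = "probs")
  if (is.null(dim(p))) {
    # two-level response: vector of P(second level)
    lev <- fit$lev
    p <- cbind(1 - p, p)
    colnames(p) <- lev
  }
  out <- p[cbind(seq_len(nrow(data)), match(as.character(observed),
                                            colnames(p)))]
  if (anyNA(out))
    stop("predicted exposure probabilities contain NA", call. = FALSE)
  out
}

#' Fit the numerator and denominator exposure models
#'
#' Pools person-period rows and fits ordinal-probability models for the
#' observed exposure level: the numerator conditions on the lagged exposure
#' and baseline covariates; the denominator adds the time-varying
#' confounders through restricted cubic spline bases. The first interval has
#' no exposure history, so lag terms are dropped there and separate
#' first-interval models are fit. Returns per-row predicted probabilities of
#' the observed exposure under each model.
#'
#' @param pp person-period table.
#' @param spec a [weight_spec()].
#' @return list with the four fitted models and aligned vectors `p_num`,
#'   `p_den`.
#' @export
fit_exposure_models <- function(pp, spec) {
  stopifnot_cols(pp, c("subject_id", "interval", spec$exposure_col,
                       spec$tv_covars), "person-period table")
  pp$..A <- factor(pp[[spec$exposure_col]],
                   levels = sort(unique(pp[[spec$exposure_col]])),
                   ordered = TRUE)
  sp <- add_spline_columns(pp, spec$tv_covars, spec$n_knots)
  pp <- sp$pp
  base_terms <- if (length(spec$baseline_covars))
    paste(spec$baseline_covars, collapse = " + ") else "1"
  f_num1 <- stats::as.formula(paste("..A ~", base_terms))
  f_den1 <- stats::as.formula(paste("..A ~", base_terms, "+",
                                    paste(sp$cols, collapse = " + ")))
  lag_terms <- paste(base_terms, "+", spec$lag_col)
  f_num2 <- stats::as.formula(paste("..A ~", lag_terms))
  f_den2 <- stats::as.formula(paste("..A ~", lag_terms, "+",
                                    paste(sp$cols, collapse = " + ")))
  k1 <- pp$interval == min(pp$interval)
  d1 <- pp[k1, , drop = FALSE]
  d2 <- pp[!k1, , drop = FALSE]
  m <- list(num_k1 = fit_categorical(f_num1, d1, spec$family),
            den_k1 = fit_categorical(f_den1, d1, spec$family))
  p_num <- p_den <- numeric(nrow(pp))
  p_num[k1] <- prob_observed(m$num_k1, d1, d1$..A)
  p_den[k1] <- prob_observed(m$den_k1, d1, d1$..A)
  if (nrow(d2)) {
    m$num_k2 <- fit_categorical(f_num2, d2, spec$family)
    m$den_k2 <- fit_categorical(f_den2, d2, spec$family)
    p_num[!k1] <- prob_observed(m$num_k2, d2, d2$..A)
    p_den[!k1] <- prob_observed(m$den_k2, d2, d2$..A)
  }
  list(models = m, p_num = p_num, p_den = p_den)
}

# Cumulative product of per-interval ratios within subject, rows assumed
# unique per (subject, interval).
cumulative_ratio <- function(pp, num, den, what) {
  bad <- which(den <= 0)
  if (length(bad))
    stop(sprintf("positivity violation: zero %s denominator probability at row %d (subject %s, interval %d)",
                 what, bad[1], pp$subject_id[bad[1]], pp$interval[bad[1]]),
         call. = FALSE)
  ord <- order(pp$subject_id, pp$interval)
  ratio <- (num / den)[ord]
  sw <- stats::ave(ratio, pp$subject_id[ord], FUN = cumprod)
  sw[order(ord)]
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Per subject-interval cumulative product over visits k <= t of the
#' numerator over denominator predicted probabilities of the observed
#' exposure.
#'
#' @param pp person-period table.
#' @param fits output of [fit_exposure_models()].
#' @return numeric vector of sw_iptw aligned with `pp` rows.
#' @export
stabilized_iptw <- function(pp, fits) {
  cumulative_ratio(pp, fits$p_num, fits$p_den, "treatment")
}

#' Fit censoring models and compute stabilized IPCW
#'
#' Pooled binary logistic models for remaining uncensored (loss to
#' follow-up only; administrative censoring at the horizon is treated as
#' non-informative and is not modeled). The numerator conditions on the
#' lagged exposure and baseline covariates; the denominator adds the
#' time-varying confounders, at the preceding visit by default, through
#' spline bases. Conditioning on the censoring history is implicit in the
#' pooled fit: rows exist only while the subject is still uncensored. With
#' no loss to follow-up in the data all weights are 1.
#'
#' @param pp person-period table with a `censor_ltfu` indicator.
#' @param spec a [weight_spec()].
#' @return list with fitted models (NULL when censoring is absent) and
#'   aligned vectors `p_num`, `p_den`, plus `sw_ipcw`.
#' @export
stabilized_ipcw <- function(pp, spec) {
  stopifnot_cols(pp, c("subject_id", "interval", "censor_ltfu"),
                 "person-period table")
  n_c <- sum(pp$censor_ltfu)
  if (n_c == nrow(pp))
    stop("degenerate censoring model: every person-period is censored",
         call. = FALSE)
  if (n_c == 0) {
    ones <- rep(1, nrow(pp))
    return(list(models = NULL, p_num = ones, p_den = ones, sw_ipcw = ones))
  }
  pp$..unc <- 1L - pp$censor_ltfu
  # time-varying confounders at the preceding visit; at the first interval
  # the preceding value is the baseline (current) one
  tv_use <- spec$tv_covars
  if (spec$censor_lag_tv) {
    ord <- order(pp$subject_id, pp$interval)
    for (col in spec$tv_covars) {
      x <- pp[[col]][ord]
      first <- !duplicated(pp$subject_id[ord])
      xl <- c(NA, x[-length(x)])
      xl[first] <- x[first]
      pp[[paste0(col, "_prev")]] <- xl[order(ord)]
    }
    tv_use <- paste0(spec$tv_covars, "_prev")
  }
  sp <- add_spline_columns(pp, tv_use, spec$n_knots)
  pp <- sp$pp
  base_terms <- if (length(spec$baseline_covars))
    paste(spec$baseline_covars, collapse = " + ") else "1"
  f_num1 <- stats::as.formula(paste("..unc ~", base_terms))
  f_den1 <- stats::as.formula(paste("..unc ~", base_terms, "+",
                                    paste(sp$cols, collapse = " + ")))
  lag_terms <- paste(base_terms, "+", spec$lag_col)
  f_num2 <- stats::as.formula(paste("..unc ~", lag_terms))
  f_den2 <- stats::as.formula(paste("..unc ~", lag_terms, "+",
                                    paste(sp$cols, collapse = " + ")))
  k1 <- pp$interval == min(pp$interval)
  d1 <- pp[k1, , drop = FALSE]
  d2 <- pp[!k1, , drop = FALSE]
  fit_or_one <- function(formula, d) {
    if (!nrow(d)) return(NULL)
    if (sum(d$..unc == 0) == 0) return("no_censoring")
    stats::glm(formula, data = d, family = stats::binomial())
  }
  pred <- function(fit, d) {
    if (is.null(fit)) return(numeric(0))
    if (identical(fit, "no_censoring")) return(rep(1, nrow(d)))
    as.numeric(stats::predict(fit, newdata = d, type = "response"))
  }
  m <- list(num_k1 = fit_or_one(f_num1, d1), den_k1 = fit_or_one(f_den1, d1),
            num_k2 = fit_or_one(f_num2, d2), den_k2 = fit_or_one(f_den2, d2))
  p_num <- p_den <- numeric(nrow(pp))
  p_num[k1] <- pred(m$num_k1, d1); p_den[k1] <- pred(m$den_k1, d1)
  p_num[!k1] <- pred(m$num_k2, d2); p_den[!k1] <- pred(m$den_k2, d2)
  sw <- cumulative_ratio(pp, p_num, p_den, "censoring")
  list(models = m, p_num = p_num, p_den = p_den, sw_ipcw = sw)
}

#' Combine and truncate stabilized weights
#'
#' Forms the final stabilized weight as the product of the treatment and
#' censoring weights and truncates it at the given percentile of the pooled
#' person-period distribution: rows at or above the percentile are assigned
#' the percentile value. Both raw and truncated values are retained.
#'
#' @param pp person-period table (for the join keys).
#' @param sw_iptw,sw_ipcw aligned weight vectors.
#' @param percentile truncation percentile (100 = no truncation).
#' @return data.frame with `subject_id`, `interval`, `sw_iptw`, `sw_ipcw`,
#'   `sw_raw`, `sw`, `truncated`.
#' @export
combine_and_truncate <- function(pp, sw_iptw, sw_ipcw, percentile = 98) {
  if (length(sw_iptw) != nrow(pp) || length(sw_ipcw) != nrow(pp))
    stop("weight vectors do not cover the person-period rows", call. = FALSE)
  sw_raw <- sw_iptw * sw_ipcw
  thr <- stats::quantile(sw_raw, percentile / 100, type = 7, names = FALSE)
  data.frame(subject_id = pp$subject_id, interval = pp$interval,
             sw_iptw = sw_iptw, sw_ipcw = sw_ipcw, sw_raw = sw_raw,
             sw = pmin(sw_raw, thr), truncated = sw_raw > thr,
             stringsAsFactors = FALSE)
}

#' Compute stabilized weights for a person-period table
#'
#' Orchestrates [fit_exposure_models()], [stabilized_iptw()],
#' [stabilized_ipcw()] and [combine_and_truncate()].
#'
#' @param pp person-period table.
#' @param spec a [weight_spec()].
#' @return the [combine_and_truncate()] table, with the fitted models
#'   attached as attribute `models`.
#' @export
compute_stabilized_weights <- function(pp, spec = weight_spec()) {
  ef <- fit_exposure_models(pp, spec)
  iptw <- stabilized_iptw(pp, ef)
  cf <- stabilized_ipcw(pp, spec)
  w <- combine_and_truncate(pp, iptw, cf$sw_ipcw,
                            spec$truncation_percentile)
  attr(w, "models") <- list(exposure = ef$models, censoring = cf$models)
  w
}

#' Descriptive statistics for stabilized weights
#'
#' Per index (when present) and per visit: min, max, mean and median of the
#' stabilized weight, with a flag for visits whose mean deviates from 1 by
#' more than 0.5 — a standard sign of weight-model misspecification.
#'
#' @param weights a weight table from [combine_and_truncate()], optionally
#'   with an `index` column.
#' @param col which weight column to summarize (truncated `sw` by default).
#' @return data.frame with one row per index and visit.
#' @export
weight_diagnostics <- function(weights, col = "sw") {
  idx <- if (is.null(weights$index)) rep("exposure", nrow(weights))
         else weights$index
  key <- split(seq_len(nrow(weights)),
               list(index = idx, visit = weights$interval), drop = TRUE)
  out <- do.call(rbind, lapply(names(key), function(k) {
    ix <- key[[k]]
    x <- weights[[col]][ix]
    data.frame(index = idx[ix[1]], visit = weights$interval[ix[1]],
               min = min(x), max = max(x), mean = mean(x),
               median = stats::median(x), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$index, out$visit), ]
  out$misspecification_flag <- abs(out$mean - 1) > 0.5
  rownames(out) <- NULL
  out
}
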