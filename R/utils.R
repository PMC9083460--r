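expit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis for a continuous covariate, with
#' knots placed at quantiles of the observed distribution. Used both in the
#' weight models (3 knots) and in the dose-response analysis (5 knots). A
#' k-knot restricted cubic spline contributes k - 1 basis columns.
#'
#' @param x numeric vector.
#' @param n_knots number of knots (>= 3).
#' @param knots optional explicit knot positions; overrides `n_knots`.
#' @return a basis matrix with an attribute `knots` giving the positions used.
#' @export
rcs_basis <- function(x, n_knots = 3, knots = NULL) {
  if (is.null(knots)) {
    probs <- switch(as.character(n_knots),
      "3" = c(0.10, 0.50, 0.90),
      "4" = c(0.05, 0.35, 0.65, 0.95),
      "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
      seq(0.05, 0.95, length.out = n_knots)
    )
    knots <- unname(stats::quantile(x, probs, na.rm = TRUE, type = 7))
  }
  knots <- sort(unique(knots))
  if (length(knots) < 3)
    stop("restricted cubic spline needs at least 3 distinct knots", call. = FALSE)
  interior <- knots[-c(1, length(knots))]
  b <- splines::ns(x, knots = interior,
                   Boundary.knots = knots[c(1, length(knots))])
  attr(b, "knots") <- knots
  b
}

# n-tile ranks with ties assigned to the lower stratum, deterministically.
# Tied values share the minimum rank, hence the lowest stratum the tie group
# touches. Errors on a constant vector (no distribution to split).
quantile_strata <- function(x, n) {
  if (anyNA(x)) stop("missing values in scores to be binned", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("degenerate score distribution: all values equal", call. = FALSE)
  if (length(x) < n)
    stop(sprintf("need at least %d observations for %d quantile strata",
                 n, n), call. = FALSE)
  r <- rank(x, ties.method = "min")
  as.integer(floor((r - 1) * n / length(x)) + 1L)
}

stopifnot_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
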