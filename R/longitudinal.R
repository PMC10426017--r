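#' Connection-weighted cumulative neighbour democracy
#'
#' For each focal nation, multiplies its row of connections by the democracy
#' scores of the other nations at the same time point and sums:
#' `value_r = sum_{k != r} W_rk * score_k`. The diagonal is zeroed first so a
#' nation's own score never enters its neighbour sum.
#'
#' @param W connection layer covering all countries in the slice.
#' @param slice named score vector from [year_slice()].
#' @return named numeric vector of weighted neighbour democracy, one entry
#'   per country in the slice.
#' @export
weighted_neighbor_democracy <- function(W, slice) {
  countries <- names(slice)
  Wc <- zero_diagonal(subset_layer(W, countries))
  stats::setNames(as.numeric(Wc %*% slice), countries)
}

#' Build a lagged diffusion dataset
#'
#' Rows are nations in existence at both T1 and T2 = T1 + lag. The outcome is
#' the democracy score at T2; predictors are the nation's own score at T1 and
#' the connection-weighted cumulative democracy of its linguistic relatives,
#' religious relatives, and geographic neighbours at T1. Neighbour sums are
#' computed over the full T1 country sample (the information available at T1)
#' and then restricted to the surviving nations. Predictors are standardised
#' by their sample standard deviation; the outcome is left on the index scale.
#'
#' @param panel a `democracy_panel`.
#' @param layers named list with elements `ling`, `rel`, `geo` (connection
#'   matrices covering the T1 countries).
#' @param T1 base year.
#' @param lag years between T1 and T2 (conventionally 5, 10, or 20; lags
#'   under 5 correlate too strongly with the outcome to be informative).
#' @return data frame of class `longitudinal_dataset` with columns `country`,
#'   `dem_T2`, `dem_T1`, `dem.ling.relatives_T1`, `dem.rel.relatives_T1`,
#'   `dem.geo.neighbours_T1`; attributes `T1`, `T2`, `sd_scale`.
#' @export
build_longitudinal_dataset <- function(panel, layers, T1, lag = 10) {
  if (lag < 1) stop("'lag' must be at least 1")
  req <- c("ling", "rel", "geo")
  if (!all(req %in% names(layers))) stop("'layers' needs elements ling, rel, geo")
  s1 <- year_slice(panel, T1)
  s2 <- year_slice(panel, T1 + lag)
  keep <- sort(intersect(names(s1), names(s2)))
  if (length(keep) < 10L) stop("insufficient sample: fewer than 10 countries at both T1 and T2")

  sums <- lapply(layers[req], weighted_neighbor_democracy, slice = s1)
  out <- data.frame(
    country = keep,
    dem_T2 = unname(s2[keep]),
    dem_T1 = unname(s1[keep]),
    stringsAsFactors = FALSE
  )
  pred_names <- c("dem.ling.relatives_T1", "dem.rel.relatives_T1", "dem.geo.neighbours_T1")
  raw <- list(out$dem_T1, sums$ling[keep], sums$rel[keep], sums$geo[keep])
  names(raw) <- c("dem_T1", pred_names)
  sds <- vapply(raw, stats::sd, numeric(1))
  for (nm in names(raw)) out[[nm]] <- scale_by_sd(unname(raw[[nm]]), nm)
  attr(out, "T1") <- as.integer(T1)
  attr(out, "T2") <- as.integer(T1 + lag)
  attr(out, "sd_scale") <- sds
  class(out) <- c("longitudinal_dataset", "data.frame")
  out
}

#' Fit the lagged diffusion (contagion) regression
#'
#' Least-squares regression of democracy at T2 on the nation's own T1 score
#' and the three standardised neighbour sums:
#' `dem_T2 ~ dem_T1 + dem.ling.relatives_T1 + dem.rel.relatives_T1 +
#' dem.geo.neighbours_T1`. Each time slice is a monadic cross-section with no
#' repeated identities, so no random effects are identifiable and plain least
#' squares is the estimator. Coefficients are per standard deviation of the
#' predictor. Perfect collinearity (e.g. from a lag too short to decorrelate
#' outcome and predictors) is flagged as non-convergence rather than raised.
#'
#' @param data a `longitudinal_dataset`.
#' @return a [fit_result] (method `"ols"`); semi-partial R-squared per
#'   predictor is available through [semipartial_r2()].
#' @export
fit_longitudinal <- function(data) {
  preds <- c("dem_T1", "dem.ling.relatives_T1", "dem.rel.relatives_T1",
             "dem.geo.neighbours_T1")
  missing <- setdiff(c("dem_T2", preds), names(data))
  if (length(missing) > 0L) {
    stop(sprintf("columns missing from data: %s", paste(missing, collapse = ", ")))
  }
  fml <- stats::as.formula(paste("dem_T2 ~", paste(preds, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  new_fit_result(fit, data = data, predictors = preds, method = "ols")
}

#' Run the diffusion analysis over a span of base years
#'
#' Convenience driver: for every T1 with both slices available, builds the
#' lagged dataset and fits the contagion regression, collecting coefficient
#' rows. Years whose dataset cannot be built (insufficient overlap) are
#' skipped silently.
#'
#' @param panel a `democracy_panel`.
#' @param layers named list with `ling`, `rel`, `geo` matrices.
#' @param lag lag in years.
#' @param years base years to attempt; default all panel years.
#' @return data frame with one row per base year and predictor: `T1`, `term`,
#'   `estimate`, `se`, `p`, `r2`, `n`, `converged`.
#' @export
run_longitudinal <- function(panel, layers, lag = 10, years = NULL) {
  years <- years %||% sort(unique(panel$year))
  rows <- list()
  for (T1 in years) {
    dat <- tryCatch(build_longitudinal_dataset(panel, layers, T1, lag),
                    error = function(e) NULL)
    if (is.null(dat)) next
    fit <- fit_longitudinal(dat)
    r2 <- if (fit$converged) semipartial_r2(fit) else NULL
    cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", , drop = FALSE]
    cf$r2 <- if (is.null(r2)) NA_real_ else unname(r2[cf$term])
    cf$T1 <- T1
    cf$n <- fit$n
    cf$converged <- fit$converged
    rows[[length(rows) + 1L]] <- cf[, c("T1", "term", "estimate", "se", "p", "r2",
                                        "n", "converged")]
  }
  do.call(rbind, rows)
}

#' Run the cross-sectional dyadic analysis over years
#'
#' For each requested year with enough countries, builds the dyadic dataset
#' (subsetting every layer to the year's sample and re-deriving the
#' geographic reversal is the caller's responsibility when layers are
#' year-specific), fits the crossed-random-intercepts model, and collects
#' coefficients with semi-partial R-squared.
#'
#' @param panel a `democracy_panel`.
#' @param layers named list of connection matrices (see
#'   [build_dyadic_dataset()]).
#' @param years years to attempt; default all panel years.
#' @param predictors fixed effects passed to [fit_dyadic_lmm()].
#' @return data frame with columns `year`, `term`, `estimate`, `se`, `p`,
#'   `r2`, `n_countries`, `n_dyads`, `converged`, `singular`.
#' @export
run_cross_sectional <- function(panel, layers, years = NULL,
                                predictors = names(layers)) {
  years <- years %||% sort(unique(panel$year))
  rows <- list()
  for (yr in years) {
    dat <- tryCatch(build_dyadic_dataset(year_slice(panel, yr), layers),
                    error = function(e) NULL)
    if (is.null(dat)) next
    fit <- fit_dyadic_lmm(dat, predictors = predictors)
    r2 <- if (fit$converged) semipartial_r2(fit) else NULL
    cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", , drop = FALSE]
    cf$r2 <- if (is.null(r2)) NA_real_ else unname(r2[cf$term])
    cf$year <- yr
    cf$n_countries <- attr(dat, "n_countries")
    cf$n_dyads <- nrow(dat)
    cf$converged <- fit$converged
    cf$singular <- fit$singular
    rows[[length(rows) + 1L]] <- cf[, c("year", "term", "estimate", "se", "p", "r2",
                                        "n_countries", "n_dyads", "converged", "singular")]
  }
  do.call(rbind, rows)
}
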