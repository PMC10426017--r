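#' Build a per-year dyadic dataset
#'
#' Converts one year's democracy scores and the connection layers into a
#' dyadic table with one row per unordered country pair: the absolute pairwise
#' difference in democracy (`dem.diff`) and the pairwise connection values of
#' each layer, taken from the lower triangles of the matrices subset to the
#' year's country sample. Every dependent and independent column is
#' standardised by dividing by its sample standard deviation (no centring).
#' Dyads are canonicalised (first country precedes the second in the slice
#' ordering), so the construction is invariant to input row or label order.
#'
#' @param slice named score vector from [year_slice()].
#' @param layers named list of connection matrices; names become predictor
#'   column names (conventionally `ling.con`, `rel.con`, `geo.prox`). Each
#'   layer must cover all countries in the slice.
#' @return data frame of class `dyadic_dataset` with columns `id_i`, `id_j`,
#'   `dem.diff`, and one standardised column per layer; attributes `year`,
#'   `n_countries`, and `sd_scale` (the divisors used).
#' @export
build_dyadic_dataset <- function(slice, layers) {
  slice <- slice[order(names(slice))] # canonical country order
  countries <- names(slice)
  n <- length(countries)
  if (n < 4L) stop("insufficient dyads: need at least 4 countries")
  if (anyDuplicated(countries)) stop("duplicate countries in slice")
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    stop("'layers' must be a named list of connection matrices")
  }

  pairs <- lower_triangle_pairs(countries)
  out <- data.frame(
    id_i = factor(pairs$j, levels = countries), # column index = first country
    id_j = factor(pairs$i, levels = countries),
    stringsAsFactors = FALSE
  )
  sds <- c()
  dd <- abs(slice[pairs$row] - slice[pairs$col])
  sds["dem.diff"] <- stats::sd(dd)
  out[["dem.diff"]] <- scale_by_sd(unname(dd), "dem.diff")
  for (nm in names(layers)) {
    M <- subset_layer(layers[[nm]], countries)
    v <- M[cbind(pairs$row, pairs$col)]
    sds[nm] <- stats::sd(v)
    out[[nm]] <- scale_by_sd(v, nm)
  }
  attr(out, "year") <- attr(slice, "year")
  attr(out, "n_countries") <- n
  attr(out, "sd_scale") <- sds
  class(out) <- c("dyadic_dataset", "data.frame")
  out
}

#' Fit the dyadic linear mixed model
#'
#' Regresses the standardised pairwise democracy difference on the requested
#' connection predictors with crossed random intercepts for the two node
#' identities, `dem.diff ~ predictors + (1|id_i) + (1|id_j)`, fitted by REML
#' through [lme4::lmer()]. The two identity factors carry separate variance
#' components. Wald two-sided p-values are reported for the fixed effects.
#' Non-convergence and singular fits are flagged on the result, never raised.
#'
#' @param data a `dyadic_dataset` (or any data frame with `id_i`, `id_j` and
#'   the model columns).
#' @param predictors character vector of fixed-effect column names; a single
#'   predictor gives the bivariate model, the default the full model.
#' @param response response column, default `"dem.diff"`.
#' @param REML fit by REML (default) or ML.
#' @return a [fit_result] object.
#' @export
fit_dyadic_lmm <- function(data,
                           predictors = intersect(c("ling.con", "rel.con", "geo.prox"),
                                                  names(data)),
                           response = "dem.diff",
                           REML = TRUE) {
  if (length(predictors) < 1L) stop("need at least one predictor")
  missing <- setdiff(c(response, predictors, "id_i", "id_j"), names(data))
  if (length(missing) > 0L) {
    stop(sprintf("columns missing from data: %s", paste(missing, collapse = ", ")))
  }
  fml <- stats::as.formula(paste(
    response, "~", paste(predictors, collapse = " + "), "+ (1 | id_i) + (1 | id_j)"
  ))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            optCtrl = list(ftol_abs = 1e-10, xtol_abs = 1e-10))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = data, REML = REML, control = ctrl)
  ))
  new_fit_result(fit, data = data, predictors = predictors,
                 method = if (REML) "lmm-reml" else "lmm-ml")
}

#' Model fit summaries for the pipeline
#'
#' A light container shared by the dyadic mixed models and the longitudinal
#' least-squares fits: fixed-effect coefficient table with Wald two-sided
#' p-values, variance components, log-likelihood, parameter count, and
#' convergence flags. Created by the fitting functions; not usually called
#' directly.
#'
#' @param model a fitted `merMod` or `lm`.
#' @param data the model data.
#' @param predictors fixed-effect terms of interest.
#' @param method label: `"lmm-reml"`, `"lmm-ml"`, or `"ols"`.
#' @return an object of class `fit_result`: a list with elements
#'   `coefficients` (data frame: term, estimate, se, stat, p), `varcomp`,
#'   `logLik`, `npar`, `n`, `converged`, `singular`, `method`, `model`.
#' @export
new_fit_result <- function(model, data, predictors, method) {
  if (inherits(model, "merMod")) {
    sm <- summary(model)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; stat <- sm[, "t value"]
    p <- 2 * stats::pnorm(-abs(stat))
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
    ll <- as.numeric(stats::logLik(model))
    npar <- attr(stats::logLik(model), "df")
    conv_msgs <- model@optinfo$conv$lme4$messages
    converged <- model@optinfo$conv$opt == 0 &&
      (is.null(conv_msgs) || !any(grepl("failed to converge", conv_msgs)))
    singular <- lme4::isSingular(model, tol = 1e-6)
    n <- stats::nobs(model)
  } else if (inherits(model, "lm")) {
    sm <- summary(model)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; stat <- sm[, "t value"]
    p <- sm[, "Pr(>|t|)"]
    rdf <- stats::df.residual(model)
    varcomp <- c(residual = sum(stats::residuals(model)^2) / rdf)
    ll <- as.numeric(stats::logLik(model))
    npar <- attr(stats::logLik(model), "df")
    converged <- !any(is.na(stats::coef(model))) && model$qr$rank == length(stats::coef(model))
    singular <- !converged
    n <- stats::nobs(model)
  } else {
    stop("unsupported model type")
  }
  structure(list(
    coefficients = data.frame(term = rownames(sm), estimate = unname(est),
                              se = unname(se), stat = unname(stat), p = unname(p),
                              row.names = NULL, stringsAsFactors = FALSE),
    varcomp = varcomp,
    logLik = ll,
    npar = npar,
    n = n,
    converged = converged,
    singular = singular,
    method = method,
    predictors = predictors,
    model = model
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, n = %d, logLik = %.3f%s%s\n", x$method, x$n,
              x$logLik,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$singular) " [singular]" else ""))
  print(x$coefficients, digits = 4)
  cat("variance components:\n")
  print(x$varcomp, digits = 4)
  invisible(x)
}

#' Coefficient accessor for fit results
#'
#' @param object a `fit_result`.
#' @param ... unused.
#' @return the coefficient data frame.
#' @export
coef.fit_result <- function(object, ...) object$coefficients

#' Semi-partial coefficients of determination
#'
#' Nakagawa-style variance-decomposition semi-partial R-squared per fixed
#' effect: the focal predictor's column is partialled on the other fixed-
#' effect columns (including the intercept), and the variance of the residual
#' column scaled by the focal coefficient is divided by the total outcome
#' variance decomposition — fixed-effect variance plus all random-intercept
#' variances plus residual variance. This measures the variance uniquely
#' attributable to each predictor after removing what the other predictors
#' explain. Works for both the crossed-random-intercepts dyadic fits and the
#' longitudinal least-squares fits (where the random-effect variance is
#' simply absent).
#'
#' @param fit a converged [fit_result].
#' @return named numeric vector of semi-partial R-squared values in `[0, 1]`,
#'   one per non-intercept fixed effect, with attribute
#'   `method = "variance-decomposition (Nakagawa-style)"`.
#' @export
semipartial_r2 <- function(fit) {
  if (!inherits(fit, "fit_result")) stop("'fit' must be a fit_result")
  if (!fit$converged) stop("cannot compute R2 for an unconverged fit")
  X <- stats::model.matrix(fit$model)
  beta <- if (inherits(fit$model, "merMod")) lme4::fixef(fit$model) else stats::coef(fit$model)
  fixed_var <- stats::var(as.numeric(X %*% beta))
  total <- fixed_var + sum(fit$varcomp)
  terms <- setdiff(colnames(X), "(Intercept)")
  out <- stats::setNames(numeric(length(terms)), terms)
  for (tm in terms) {
    others <- X[, setdiff(colnames(X), tm), drop = FALSE]
    r <- stats::residuals(stats::lm.fit(others, X[, tm]))
    out[tm] <- min(1, max(0, beta[tm]^2 * stats::var(r) / total))
  }
  attr(out, "method") <- "variance-decomposition (Nakagawa-style)"
  out
}

#' Small-sample corrected AIC for one fit
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`, with k counting every
#' estimated parameter (fixed effects, variance components, residual
#' variance). Mixed models fitted by REML are automatically refitted by ML
#' first, since likelihoods of REML fits with different fixed effects are not
#' comparable.
#'
#' @param fit a [fit_result].
#' @return the AICc value (scalar).
#' @export
aicc <- function(fit) {
  if (!inherits(fit, "fit_result")) stop("'fit' must be a fit_result")
  model <- fit$model
  if (inherits(model, "merMod") && lme4::isREML(model)) {
    model <- lme4::refitML(model)
  }
  ll <- stats::logLik(model)
  k <- attr(ll, "df")
  n <- stats::nobs(model)
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc
#'
#' All fits must be on the identical rows; mixed models are refitted by ML
#' before comparison (see [aicc()]).
#'
#' @param fits named list of [fit_result] objects on the same data.
#' @return data frame ranked by AICc with columns `model`, `k`, `logLik_ml`,
#'   `AICc`, `dAICc`.
#' @export
aicc_compare <- function(fits) {
  if (!is.list(fits) || length(fits) < 1L) stop("'fits' must be a non-empty list")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L) stop("all fits must use the identical dataset rows")
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  rows <- lapply(seq_along(fits), function(idx) {
    f <- fits[[idx]]
    model <- f$model
    if (inherits(model, "merMod") && lme4::isREML(model)) model <- lme4::refitML(model)
    ll <- stats::logLik(model)
    data.frame(model = nm[idx], k = attr(ll, "df"), logLik_ml = as.numeric(ll),
               AICc = aicc(f), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$AICc), , drop = FALSE]
  out$dAICc <- out$AICc - out$AICc[1]
  rownames(out) <- NULL
  out
}

#' Export residuals and fitted values
#'
#' @param fit a [fit_result].
#' @return data frame with columns `fitted`, `residual`.
#' @export
residual_table <- function(fit) {
  data.frame(fitted = stats::fitted(fit$model),
             residual = stats::residuals(fit$model))
}
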