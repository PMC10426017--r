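make_slice <- function(scores, year = 2000L) {
  s <- scores
  attr(s, "year") <- year
  attr(s, "convention") <- "polity2"
  s
}

make_layers <- function(countries, seed = 1) {
  set.seed(seed)
  lapply(c(ling.con = 1, rel.con = 2, geo.prox = 3), function(k) {
    n <- length(countries)
    M <- matrix(runif(n * n), n, dimnames = list(countries, countries))
    M <- (M + t(M)) / 2
    diag(M) <- 0
    M
  })
}

test_that("dyadic datasets enumerate all unordered pairs, standardised to unit SD", {
  for (n in c(4, 7, 12)) {
    countries <- sprintf("C%02d", seq_len(n))
    slice <- make_slice(stats::setNames(seq_len(n) * 1.7, countries))
    layers <- make_layers(countries, seed = n)
    d <- build_dyadic_dataset(slice, layers)
    expect_equal(nrow(d), n * (n - 1) / 2)
    for (col in c("dem.diff", "ling.con", "rel.con", "geo.prox")) {
      # independent SD formula (n-1 denominator, no centring applied before)
      v <- d[[col]]
      expect_equal(sqrt(sum((v - mean(v))^2) / (length(v) - 1)), 1,
                   tolerance = 1e-10)
    }
  }
})

test_that("dyadic rows equal the brute-force all-pairs loop", {
  countries <- sprintf("C%02d", 1:6)
  slice <- make_slice(stats::setNames(c(0, 5, 10, -3, 7, 2), countries))
  layers <- make_layers(countries, seed = 5)
  d <- build_dyadic_dataset(slice, layers)
  o <- oracle_dyads(slice, layers)
  sds <- attr(d, "sd_scale")
  # undo the standardisation and compare raw values pair by pair
  key <- function(df) paste(df$id_i, df$id_j)
  expect_setequal(key(d), key(o))
  o <- o[match(key(d), key(o)), ]
  expect_equal(d$dem.diff * sds["dem.diff"], o$dem.diff,
               tolerance = 1e-12, ignore_attr = TRUE)
  for (nm in names(layers)) {
    expect_equal(d[[nm]] * sds[nm], o[[nm]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("absolute democracy differences enter before scaling", {
  countries <- c("A", "B", "C", "D")
  slice <- make_slice(stats::setNames(c(0, 5, 10, 0), countries))
  d <- build_dyadic_dataset(slice, make_layers(countries))
  raw <- d$dem.diff * attr(d, "sd_scale")["dem.diff"]
  lookup <- stats::setNames(raw, paste(d$id_i, d$id_j))
  expect_equal(unname(lookup[c("A B", "A C", "B C")]), c(5, 10, 5))
})

test_that("degenerate dyadic inputs are rejected", {
  countries <- c("A", "B", "C")
  slice <- make_slice(stats::setNames(1:3, countries))
  expect_error(build_dyadic_dataset(slice, make_layers(countries)),
               "insufficient dyads")
  countries <- c("A", "B", "C", "D")
  flat <- make_slice(stats::setNames(rep(1, 4), countries))
  expect_error(build_dyadic_dataset(flat, make_layers(countries)), "dem.diff")
})

test_that("fits are invariant to country and row order", {
  set.seed(31)
  countries <- sprintf("C%02d", 1:12)
  slice <- make_slice(stats::setNames(rnorm(12, 0, 5), countries))
  layers <- make_layers(countries, seed = 8)
  f1 <- fit_dyadic_lmm(build_dyadic_dataset(slice, layers))
  perm <- sample(12)
  f2 <- fit_dyadic_lmm(build_dyadic_dataset(slice[perm],
                                            lapply(layers, function(M) M[perm, perm])))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate, tolerance = 1e-8)
  expect_equal(sort(f1$varcomp), sort(f2$varcomp), tolerance = 1e-6)
})

test_that("with no node effects the mixed model collapses to least squares", {
  d <- simulate_dyadic(n_countries = 25, beta = c(ling.con = 0.5, rel.con = -0.3),
                       re_sd = 0, resid_sd = 1, seed = 4)
  fit <- fit_dyadic_lmm(d, predictors = c("ling.con", "rel.con"))
  ols <- stats::lm(dem.diff ~ ling.con + rel.con, data = d)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)
  expect_true(fit$singular) # zero variance components sit on the boundary
})

test_that("bivariate and full fixed-effect structures are both supported", {
  d <- simulate_dyadic(n_countries = 20, seed = 9)
  full <- fit_dyadic_lmm(d)
  expect_equal(full$coefficients$term,
               c("(Intercept)", "ling.con", "rel.con", "geo.prox"))
  biv <- fit_dyadic_lmm(d, predictors = "ling.con")
  expect_equal(biv$coefficients$term, c("(Intercept)", "ling.con"))
  expect_named(full$varcomp, c("id_i", "id_j", "residual"), ignore.order = TRUE)
  expect_true(all(is.finite(full$coefficients$p)))
})

test_that("semi-partial R2 hits the saturated and null limits", {
  set.seed(12)
  d <- simulate_dyadic(n_countries = 30, beta = c(ling.con = 0.8),
                       re_sd = 0, resid_sd = 1e-8, seed = 12)
  fit <- fit_dyadic_lmm(d, predictors = "ling.con")
  r2 <- semipartial_r2(fit)
  expect_gt(r2[["ling.con"]], 0.999) # noiseless single predictor
  expect_lte(r2[["ling.con"]], 1)

  d0 <- simulate_dyadic(n_countries = 30, beta = c(ling.con = 0),
                        re_sd = 0.4, resid_sd = 1, seed = 13)
  f0 <- fit_dyadic_lmm(d0, predictors = "ling.con")
  expect_lt(semipartial_r2(f0)[["ling.con"]], 0.05)
})

test_that("stronger generative effects yield larger semi-partial R2", {
  meds <- vapply(c(0.2, 0.5, 0.8), function(b) {
    r2s <- vapply(1:12, function(s) {
      d <- simulate_dyadic(n_countries = 25, beta = c(ling.con = b, rel.con = 0.2),
                           re_sd = 0.3, resid_sd = 1, seed = 100 * b + s)
      semipartial_r2(fit_dyadic_lmm(d, predictors = c("ling.con", "rel.con")))[["ling.con"]]
    }, numeric(1))
    stats::median(r2s)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("AICc applies the small-sample correction and ranks the true model first", {
  d <- simulate_dyadic(n_countries = 30, beta = c(ling.con = 0.6, rel.con = 0.4),
                       re_sd = 0.3, resid_sd = 1, seed = 21)
  full <- fit_dyadic_lmm(d, predictors = c("ling.con", "rel.con"))
  same <- fit_dyadic_lmm(d, predictors = c("ling.con", "rel.con"))
  cmp_same <- aicc_compare(list(a = full, b = same))
  expect_equal(cmp_same$dAICc, c(0, 0), tolerance = 1e-6)

  # AICc exceeds AIC for finite n
  ml <- lme4::refitML(full$model)
  expect_gt(aicc(full), stats::AIC(ml))

  red <- fit_dyadic_lmm(d, predictors = "rel.con")
  cmp <- aicc_compare(list(full = full, reduced = red))
  expect_equal(cmp$model[1], "full")
  expect_error(aicc_compare(list(full, fit_dyadic_lmm(d[-1, ]))), "identical dataset")
})

test_that("model selection prefers the generating model in most replicates", {
  wins <- vapply(1:40, function(s) {
    d <- simulate_dyadic(n_countries = 25, beta = c(ling.con = 0.5, rel.con = 0.3),
                         re_sd = 0.3, resid_sd = 1, seed = 500 + s)
    full <- fit_dyadic_lmm(d, predictors = c("ling.con", "rel.con"))
    red <- fit_dyadic_lmm(d, predictors = "rel.con")
    aicc_compare(list(full = full, reduced = red))$model[1] == "full"
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("residual export matches the fitted model", {
  d <- simulate_dyadic(n_countries = 15, seed = 3)
  fit <- fit_dyadic_lmm(d)
  rt <- residual_table(fit)
  expect_equal(nrow(rt), nrow(d))
  expect_equal(rt$fitted + rt$residual, d$dem.diff, tolerance = 1e-8)
})
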