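test_that("univariate screening recognises strong functional forms", {
  bins <- small_bins(n_cruises = 12, bins_per_cruise = 150, seed = 301)
  # strong quadratic SST response (vertex inside the observed range)
  bins$sst2 <- bins$sst^2
  d <- generate_counts(bins, true_model(
    "NB", c("(Intercept)" = -25, sst = 4.1, sst2 = -0.1665), alpha = 0.6),
    seed = 302)
  tm <- select_univariate_form("sst", "oceanographic", d)
  expect_s3_class(tm, "model_term")
  expect_equal(tm$form, "quadratic")

  # moderate log response to the isobath distance (strong saturating
  # effects make the monotone log-family forms indistinguishable)
  d2 <- bins
  d2$log_d200 <- log(bins$dist_200m + 1)
  d2 <- generate_counts(d2, true_model(
    "NB", c("(Intercept)" = 1, log_d200 = -0.4), alpha = 0.6), seed = 303)
  tm2 <- select_univariate_form("dist_200m", "distance", d2)
  expect_s3_class(tm2, "model_term")
  expect_equal(tm2$form, "log")
})

test_that("climate screening finds the generating lag", {
  bins <- small_bins(n_cruises = 30, bins_per_cruise = 60,
                     years = 2004:2009, seed = 311)
  d <- generate_counts(bins, true_model(
    "NB", c("(Intercept)" = 0.3, pdo_lag3 = 0.9), alpha = 0.6), seed = 312)
  tm <- select_univariate_form("pdo", "climate", d)
  expect_s3_class(tm, "model_term")
  expect_equal(tm$variable, "pdo")
  expect_equal(tm$lag, 3L)
})

test_that("backward stepwise keeps true effects, culls noise, and flags VIF", {
  bins <- small_bins(n_cruises = 15, bins_per_cruise = 150, seed = 321)
  d <- generate_counts(bins, true_model(
    "NB", c("(Intercept)" = -1.2, sst = 0.25, dist_200m = -0.08),
    alpha = 0.6), seed = 322)

  # a single strongly significant term is a fixed point
  one <- backward_stepwise(list(model_term("sst")), d)
  expect_length(one$terms, 1L)
  expect_equal(one$terms[[1]]$variable, "sst")
  expect_false(attr(one, "controls_only"))

  # true effects survive among noise covariates
  cand <- list(model_term("sst"), model_term("dist_200m"),
               model_term("ssf"), model_term("dist_island"),
               model_term("cloud_cover"))
  fit <- backward_stepwise(cand, d)
  kept <- vapply(fit$terms, function(t) t$variable, character(1))
  expect_true(all(c("sst", "dist_200m") %in% kept))
  # final model never contains a non-significant term
  ps <- vapply(fit$terms, function(tm) foragedist:::term_p(fit, tm),
               numeric(1))
  expect_true(all(ps < 0.05))
  # protocol determinism: identical rerun gives the identical model
  fit2 <- backward_stepwise(cand, d)
  expect_equal(fit$coefficients, fit2$coefficients)

  # a perfect duplicate of a retained covariate is evicted by the VIF rule
  d$sst_copy <- d$sst
  fit3 <- backward_stepwise(c(cand, list(model_term("sst_copy"))), d)
  kept3 <- vapply(fit3$terms, function(t) t$variable, character(1))
  expect_false(all(c("sst", "sst_copy") %in% kept3))
})

test_that("noise-only candidates collapse to the controls-only model", {
  bins <- small_bins(n_cruises = 10, bins_per_cruise = 120, seed = 331)
  d <- generate_counts(bins, true_model(
    "NB", c("(Intercept)" = 0), alpha = 0.6), seed = 332)
  fit <- suppressWarnings(
    backward_stepwise(list(model_term("cloud_cover"),
                           model_term("dist_island")), d)
  )
  # either everything is culled (flagged) or any survivor is significant
  if (attr(fit, "controls_only")) {
    expect_length(fit$terms, 0L)
  } else {
    ps <- vapply(fit$terms, function(tm) foragedist:::term_p(fit, tm),
                 numeric(1))
    expect_true(all(ps < 0.05))
  }
})

test_that("year interactions are detected and absent candidates skipped", {
  bins <- small_bins(n_cruises = 16, bins_per_cruise = 150,
                     years = 2004:2005, seed = 341)
  # SST slope differs strongly between the two years
  slope <- ifelse(bins$year == 2004, 0.35, -0.1)
  mu <- exp(-1 + slope * bins$sst + log(bins$area_km2))
  d <- bins
  d$count <- with_seed_test(342,
                            stats::rnbinom(nrow(d), mu = mu, size = 1 / 0.5))
  base <- fit_nb(list(model_term("sst")), d)
  ext <- add_year_interactions(base, d)
  expect_true("sst:factor(year)" %in% attr(ext, "interactions"))

  # candidate absent from the model is skipped, not force-added
  base2 <- fit_nb(list(model_term("dist_cordell")), d)
  ext2 <- add_year_interactions(base2, d)
  expect_length(attr(ext2, "interactions"), 0L)
  expect_equal(ext2$coefficients, base2$coefficients)
})

test_that("inflation choice keeps ZINB only when zeros are structural", {
  bins <- small_bins(n_cruises = 15, bins_per_cruise = 150, seed = 351)
  zt <- true_model(
    "ZINB", c("(Intercept)" = 0.6, sst = 0.12),
    inflation_coefficients = c("(Intercept)" = -1.5, sea_state = 0.9),
    alpha = 0.8)
  dz <- generate_counts(bins, zt, seed = 352)
  base <- fit_nb(list(model_term("sst")), dz)
  chosen <- choose_inflation(base, dz)
  expect_equal(chosen$family, "zinb")
  expect_true("sea_state" %in% attr(chosen, "detection_variables"))

  dn <- generate_counts(bins, true_model(
    "NB", c("(Intercept)" = 0.6, sst = 0.12), alpha = 0.8), seed = 353)
  base_n <- fit_nb(list(model_term("sst")), dn)
  chosen_n <- choose_inflation(base_n, dn)
  expect_equal(chosen_n$family, "nb")
})

test_that("dominant climate index is the strongest contributor", {
  bins <- small_bins(n_cruises = 30, bins_per_cruise = 80,
                     years = 2004:2009, seed = 361)
  d <- generate_counts(bins, true_model(
    "NB", c("(Intercept)" = 0.2, pdo_lag0 = 0.9, soi_lag0 = 0.1),
    alpha = 0.5), seed = 362)
  fit <- fit_nb(list(model_term("pdo", lag = 0), model_term("soi", lag = 0)),
                d)
  dom <- dominant_climate_index(fit, d)
  expect_equal(as.character(dom), "pdo")

  # a single retained index is returned directly
  fit1 <- fit_nb(list(model_term("pdo", lag = 0)), d)
  expect_equal(as.character(dominant_climate_index(fit1, d)), "pdo")

  # no climate index: error
  fit0 <- fit_nb(list(model_term("sst")), d)
  expect_error(dominant_climate_index(fit0, d), "climate")

  # exactly symmetric design (duplicated index columns) reports a tie
  d$soi_lag0 <- d$pdo_lag0
  fit_t <- suppressWarnings(
    fit_nb(list(model_term("pdo", lag = 0), model_term("soi", lag = 0)), d))
  expect_warning(dom_t <- dominant_climate_index(fit_t, d), "tie")
  expect_setequal(as.character(dom_t), c("pdo", "soi"))
})
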