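test_that("NB fit recovers generating parameters and honours the offset", {
  bins <- small_bins(n_cruises = 10, bins_per_cruise = 200, seed = 201)
  truth <- true_model("NB", c("(Intercept)" = -1.5, sst = 0.12,
                              dist_200m = -0.05), alpha = 0.8)
  bins <- generate_counts(bins, truth, seed = 202)
  fit <- fit_nb(list(model_term("sst"), model_term("dist_200m")), bins,
                controls = FALSE)
  expect_s3_class(fit, "count_fit")
  expect_true(fit$converged)
  for (nm in names(truth$coefficients)) {
    expect_lt(abs(fit$coefficients[nm] - truth$coefficients[nm]),
              3 * fit$se[nm])
  }
  # doubling all areas leaves slopes and intercept unchanged
  bins2 <- bins
  bins2$area_km2 <- bins$area_km2 * 2
  bins2$count <- with_seed_test(203, {
    mu <- exp(-1.5 + 0.12 * bins2$sst - 0.05 * bins2$dist_200m) *
      bins2$area_km2
    stats::rnbinom(nrow(bins2), mu = mu, size = 1 / 0.8)
  })
  fit2 <- fit_nb(list(model_term("sst"), model_term("dist_200m")), bins2,
                 controls = FALSE)
  for (nm in names(truth$coefficients)) {
    expect_lt(abs(fit2$coefficients[nm] - truth$coefficients[nm]),
              3 * fit2$se[nm])
  }
})

test_that("ZINB fit recovers count and inflation coefficients", {
  bins <- small_bins(n_cruises = 15, bins_per_cruise = 200, seed = 211)
  truth <- true_model(
    "ZINB", c("(Intercept)" = 0.3, sst = 0.12),
    inflation_coefficients = c("(Intercept)" = -1, sea_state = 0.6),
    alpha = 1
  )
  bins <- generate_counts(bins, truth, seed = 212)
  fit <- fit_zinb(list(model_term("sst")),
                  list(model_term("sea_state", role = "inflation")),
                  bins, controls = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients["sst"] - 0.12), 3 * fit$se["sst"])
  expect_lt(abs(fit$inflation_coefficients["sea_state"] - 0.6),
            3 * fit$inflation_se["sea_state"])

  # constant inflation covariate collapses to an intercept-only logit and
  # count coefficients stay close to the plain NB fit on NB data
  nb_data <- generate_counts(bins, true_model(
    "NB", c("(Intercept)" = 0.3, sst = 0.12), alpha = 1), seed = 213)
  nb_data$const_det <- 1
  fz <- fit_zinb(list(model_term("sst")),
                 list(model_term("const_det", role = "inflation")),
                 nb_data, controls = FALSE)
  expect_length(fz$inflation_coefficients, 1L)
  fn <- fit_nb(list(model_term("sst")), nb_data, controls = FALSE)
  expect_lt(abs(fz$coefficients["sst"] - fn$coefficients["sst"]),
            2 * fn$se["sst"])

  zero <- nb_data
  zero$count <- 0L
  expect_error(fit_zinb(list(model_term("sst")), list(), zero),
               "unidentifiable")
})

test_that("boundary LR test of alpha behaves under null and alternative", {
  # strongly over-dispersed data: decisive rejection
  bins <- nb_bins(seed = 221, n_cruises = 20, bins_per_cruise = 200,
                  alpha = 1)
  fit <- fit_nb(list(model_term("sst")), bins)
  lt <- lr_test_alpha(fit, bins)
  expect_lt(lt$p_value, 1e-6)

  # Poisson data: alpha estimate near zero, moderate rejection rate
  pois <- small_bins(n_cruises = 10, bins_per_cruise = 100, seed = 222)
  rejections <- vapply(1:40, function(s) {
    d <- generate_counts(pois, true_model(
      "NB", c("(Intercept)" = 0.5, sst = 0.05), alpha = 0), seed = 2000 + s)
    f <- suppressWarnings(fit_nb(list(model_term("sst")), d,
                                 controls = FALSE, compute_null = FALSE))
    lr_test_alpha(f, d)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.10)
})

test_that("Vuong statistic follows its formula and flags degenerate input", {
  bins <- small_bins(n_cruises = 10, bins_per_cruise = 150, seed = 231)
  truth <- true_model(
    "ZINB", c("(Intercept)" = 0.5, sst = 0.1),
    inflation_coefficients = c("(Intercept)" = 0), alpha = 1)
  bins <- generate_counts(bins, truth, seed = 232)
  fn <- fit_nb(list(model_term("sst")), bins, controls = FALSE)
  fz <- fit_zinb(list(model_term("sst")), list(), bins, controls = FALSE)
  vt <- vuong_test(fn, fz, bins)
  # independent recomputation from per-observation likelihoods
  m <- foragedist:::ll_obs(fz, bins) - foragedist:::ll_obs(fn, bins)
  expect_equal(vt$statistic, sqrt(length(m)) * mean(m) / stats::sd(m),
               tolerance = 1e-10)
  expect_equal(vt$p_value, stats::pnorm(vt$statistic, lower.tail = FALSE))
  expect_error(vuong_test(fn, structure(fn, family = "zinb"), bins))
})

test_that("VIF matches its closed form and flags perfect collinearity", {
  X <- with_seed_test(241, cbind(a = stats::rnorm(4000),
                                 b = stats::rnorm(4000)))
  # orthogonal columns: VIF ~ 1
  v0 <- vif(X)
  expect_true(all(abs(v0 - 1) < 0.05))
  # correlation 0.9 gives VIF 1/(1-0.81) ~ 5.263
  X2 <- with_seed_test(242, {
    z <- stats::rnorm(20000)
    a <- z
    b <- 0.9 * z + sqrt(1 - 0.81) * stats::rnorm(20000)
    cbind(a = a, b = b)
  })
  v2 <- vif(X2)
  expect_equal(unname(v2), rep(1 / (1 - cor(X2[, 1], X2[, 2])^2), 2),
               tolerance = 1e-6)
  expect_lt(abs(v2[["a"]] - 5.263), 0.3)
  # duplicated column: infinite VIF
  X3 <- cbind(X2, a2 = X2[, "a"])
  expect_true(any(is.infinite(vif(X3))))
})

test_that("McFadden pseudo-R2 and nesting invariants hold", {
  bins <- nb_bins(seed = 251, n_cruises = 10, bins_per_cruise = 150)
  null_fit <- fit_count_model(list(), bins, "nb", controls = FALSE)
  expect_equal(null_fit$pseudo_r2, 0)
  fit1 <- fit_nb(list(model_term("sst")), bins)
  fit2 <- fit_nb(list(model_term("sst"), model_term("dist_200m")), bins)
  expect_gte(fit1$pseudo_r2, 0)
  expect_lt(fit1$pseudo_r2, 1)
  expect_equal(fit1$pseudo_r2,
               1 - fit1$log_likelihood / fit1$null_log_likelihood)
  # adding a term never decreases the log-likelihood of a nested fit
  expect_gte(fit2$log_likelihood, fit1$log_likelihood - 1e-6)
  expect_gte(fit1$log_likelihood, fit1$null_log_likelihood - 1e-6)
})

test_that("count_fit methods are coherent", {
  bins <- nb_bins(seed = 261, n_cruises = 8, bins_per_cruise = 120)
  fit <- fit_nb(list(model_term("sst")), bins)
  expect_output(print(fit), "NB count model")
  expect_output(print(summary(fit)), "pseudo-R2")
  expect_named(coef(fit))
  expect_equal(dim(vcov(fit)), rep(length(coef(fit)), 2))
  expect_equal(as.numeric(logLik(fit)), fit$log_likelihood)
  expect_length(residuals(fit, data = bins), nrow(bins))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(sims, simulate(fit, nsim = 2, seed = 9))
  expect_true(all(sims >= 0))
  expect_equal(length(fitted(fit)), nrow(bins))
})
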