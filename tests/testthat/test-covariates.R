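test_that("contour index follows its formula and is scale-invariant", {
  expect_equal(contour_index(c(100, 50)), 0.5)
  expect_equal(contour_index(c(80, 80, 80)), 0)
  # arithmetic on the envelope extremes of the depth covariate
  expect_equal(contour_index(c(2075.6, 7.6)), (2075.6 - 7.6) / 2075.6)
  expect_error(contour_index(numeric(0)), "non-empty")
  expect_error(contour_index(c(10, -5)), "positive")
  for (s in 1:5) {
    d <- with_seed_test(s, stats::runif(10, 5, 500))
    expect_equal(contour_index(d * 3.7), contour_index(d))
  }
})

test_that("lag_series does calendar arithmetic with year rollover", {
  months <- expand.grid(month = 1:12, year = 2004:2006)
  raw <- data.frame(year = months$year, month = months$month,
                    pdo = seq_len(nrow(months)))
  expect_identical(lag_series(raw, 0), raw)
  l3 <- lag_series(raw, 3)
  jan05 <- l3$pdo[l3$year == 2005 & l3$month == 1]
  oct04 <- raw$pdo[raw$year == 2004 & raw$month == 10]
  expect_equal(jan05, oct04)
  # lag 3 twice == lag 6 once on the overlapping rows
  l33 <- lag_series(lag_series(raw, 3), 3)
  l6 <- lag_series(raw, 6)
  common <- merge(l33, l6, by = c("year", "month"))
  expect_equal(common$pdo.x, common$pdo.y)
})

test_that("ordinary kriging is exact, unbiased for constants, and handles trends", {
  vg <- list(nugget = 0, psill = 1, range = 5)
  for (s in 1:3) {
    samples <- with_seed_test(s, data.frame(
      x = stats::runif(25, 0, 20), y = stats::runif(25, 0, 20)
    ))
    samples$value <- cos(samples$x / 3) + 0.05 * samples$y
    # zero-nugget prediction at sampled locations returns the samples
    back <- krige_surface(samples, samples[, c("x", "y")], variogram = vg,
                          detrend = "never")
    expect_equal(back$value, samples$value, tolerance = 1e-8)
    # constant fields predict the constant everywhere (weights sum to 1)
    const <- samples
    const$value <- 42
    grid <- unit_lattice(10, 10)
    k <- krige_surface(const, grid, variogram = vg, detrend = "never")
    expect_equal(k$value, rep(42, nrow(grid)), tolerance = 1e-8)
    expect_true(all(k$se >= 0))
  }
})

test_that("detrended kriging recovers a planar field", {
  samples <- with_seed_test(9, data.frame(
    x = stats::runif(30, 0, 20), y = stats::runif(30, 0, 20)
  ))
  samples$value <- 2 + 0.3 * samples$x - 0.5 * samples$y
  grid <- unit_lattice(20, 20)
  k <- suppressWarnings(krige_surface(samples, grid, detrend = "auto"))
  truth <- 2 + 0.3 * grid$x - 0.5 * grid$y
  rmse <- sqrt(mean((k$value - truth)^2))
  expect_lt(rmse, 0.01 * diff(range(truth)))
  expect_true(attr(k, "detrended"))
})

test_that("kriging input validation", {
  g <- unit_lattice(3, 3)
  few <- data.frame(x = 1:3, y = 1:3, value = 1:3)
  expect_error(krige_surface(few, g), ">= 5")
  dup <- data.frame(x = c(1, 1, 2, 3, 4), y = c(1, 1, 2, 3, 4),
                    value = c(1, 9, 2, 3, 4))
  expect_error(krige_surface(dup, g, detrend = "never"), "conflicting")
})

test_that("surface filter rejects exactly the 3-SD outliers", {
  # hand computation: 20 surfaces at mean SE 1 plus one at 100
  ses <- c(rep(1, 20), 100)
  m <- mean(ses)
  s <- stats::sd(ses)
  expect_true(abs(100 - m) > 3 * s)  # the outlier is outside the band
  expect_true(abs(1 - m) < 3 * s)    # the others are inside
  res <- filter_surfaces(ses)
  expect_equal(res$rejected, 21L)
  expect_equal(res$accepted, 1:20)

  # identical surfaces are all accepted; a single surface errors
  expect_length(filter_surfaces(rep(2, 5))$rejected, 0)
  expect_error(filter_surfaces(3), "2 surfaces")

  # homogeneous batches are rarely rejected (< 1% over simulated batches)
  rej <- with_seed_test(13, {
    mean(replicate(200, {
      length(filter_surfaces(stats::rnorm(30, 1, 0.1))$rejected) > 0
    }))
  })
  expect_lt(rej, 0.05)
})

test_that("TSG gap-fill regression recovers the calibration", {
  n <- 300
  base <- with_seed_test(17, {
    d <- data.frame(x = stats::runif(n, 0, 10), y = stats::runif(n, 0, 10),
                    month = sample(4:10, n, TRUE),
                    year = sample(2004:2006, n, TRUE))
    d$ctd <- stats::rnorm(n, 12, 1.5)
    d
  })
  ctd <- data.frame(x = base$x, y = base$y, month = base$month,
                    year = base$year, value = base$ctd)

  # exact relation: predictions equal CTD values, R^2 = 1
  tsg <- data.frame(x = base$x, y = base$y, month = base$month,
                    year = base$year, value = base$ctd)
  tsg$value[1:10] <- NA
  res <- suppressWarnings(fill_missing_tsg(tsg, ctd))  # perfect-fit note
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_equal(res$predictions$fill, base$ctd[1:10], tolerance = 1e-6)

  # noisy linear relation: slope recovered
  tsg2 <- tsg
  tsg2$value <- with_seed_test(18, 2 * base$ctd + 1 + stats::rnorm(n, 0, 0.01))
  tsg2$value[1:10] <- NA
  res2 <- fill_missing_tsg(tsg2, ctd)
  expect_lt(abs(unname(stats::coef(res2$model)["ctd_value"]) - 2), 0.01)

  # a gap far from every CTD cast is flagged unfillable
  tsg3 <- tsg2
  tsg3$x[1] <- 500
  res3 <- fill_missing_tsg(tsg3, ctd)
  expect_false(res3$predictions$fillable[1])
  expect_true(is.na(res3$predictions$fill[1]))
})

test_that("gap-fill R^2 matches the generating signal-to-noise ratio", {
  # population R^2 tuned to 0.94: var(signal) / (var(signal) + var(noise))
  n <- 800
  sd_sig <- 1.5
  sd_noise <- sd_sig * sqrt(1 / 0.94 - 1)
  d <- with_seed_test(19, {
    ctd_v <- stats::rnorm(n, 12, sd_sig)
    data.frame(x = stats::runif(n, 0, 10), y = stats::runif(n, 0, 10),
               month = sample(4:10, n, TRUE), year = 2004,
               ctd_v = ctd_v,
               tsg_v = ctd_v + stats::rnorm(n, 0, sd_noise))
  })
  ctd <- data.frame(x = d$x, y = d$y, month = d$month, year = d$year,
                    value = d$ctd_v)
  tsg <- data.frame(x = d$x, y = d$y, month = d$month, year = d$year,
                    value = d$tsg_v)
  res <- fill_missing_tsg(tsg, ctd)
  expect_lt(abs(res$r_squared - 0.94), 0.02)
})
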