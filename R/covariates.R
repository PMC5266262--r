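#' Seafloor contour index
#'
#' Ocean-floor complexity of a bin: `(max depth - min depth) / max depth`,
#' with depths positive-down. Scale-invariant and in `[0, 1)`.
#'
#' @param depths positive depths (m) observed within one bin.
#' @return scalar contour index.
#' @export
contour_index <- function(depths) {
  if (length(depths) == 0L || !is.numeric(depths)) {
    stop("`depths` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(depths <= 0)) {
    stop("depths must be positive (positive-down convention)", call. = FALSE)
  }
  (max(depths) - min(depths)) / max(depths)
}

#' Lag a monthly index series
#'
#' Shifts every index column so the value reported for `(year, month)` is
#' the raw value at `(year, month - lag)`, with correct December to
#' January rollover.
#'
#' @param raw data.frame with `year`, `month` and index columns.
#' @param lag non-negative integer number of months.
#' @return data.frame with the same columns; rows whose lagged month falls
#'   before the start of `raw` are dropped.
#' @export
lag_series <- function(raw, lag) {
  stopifnot(is.data.frame(raw), all(c("year", "month") %in% names(raw)),
            lag >= 0, lag == as.integer(lag))
  if (lag == 0L) return(raw)
  key <- 12L * raw$year + (raw$month - 1L)
  src <- match(key - as.integer(lag), key)
  out <- raw
  vals <- setdiff(names(raw), c("year", "month"))
  for (v in vals) out[[v]] <- raw[[v]][src]
  out[!is.na(src), , drop = FALSE]
}

# ---- ordinary kriging --------------------------------------------------

expo_semivariance <- function(h, nugget, psill, range) {
  nugget * (h > 0) + psill * (1 - exp(-h / range))
}

#' Empirical semivariogram
#'
#' Binned empirical semivariances `0.5 * mean((z_i - z_j)^2)` of all point
#' pairs up to half the maximum separation.
#'
#' @param x,y,value sample coordinates (km) and values.
#' @param n_bins number of distance bins.
#' @return data.frame `dist`, `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(x, y, value, n_bins = 12L) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  g <- 0.5 * outer(value, value, "-")^2
  keep <- upper.tri(d)
  dv <- d[keep]
  gv <- g[keep]
  max_d <- max(dv) / 2
  sel <- dv > 0 & dv <= max_d
  dv <- dv[sel]; gv <- gv[sel]
  br <- seq(0, max_d, length.out = n_bins + 1L)
  bin <- cut(dv, br, include.lowest = TRUE)
  out <- data.frame(
    dist = tapply(dv, bin, mean),
    gamma = tapply(gv, bin, mean),
    n_pairs = as.integer(table(bin))
  )
  out <- out[!is.na(out$dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit an exponential variogram model by weighted least squares
#'
#' Weights are pair counts per distance bin.
#'
#' @param emp empirical semivariogram from [empirical_variogram()].
#' @return list `nugget`, `psill`, `range` (all positive, nugget >= 0).
#' @export
fit_variogram <- function(emp) {
  stopifnot(nrow(emp) >= 3L)
  s0 <- max(stats::var(emp$gamma), max(emp$gamma) * 0.5, 1e-10)
  start <- c(nugget = 0, psill = max(emp$gamma), range = max(emp$dist) / 3)
  obj <- function(p) {
    fit <- expo_semivariance(emp$dist, p[1], p[2], p[3])
    sum(emp$n_pairs * (emp$gamma - fit)^2)
  }
  res <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 1e-10, max(emp$dist) * 1e-3))
  as.list(res$par)
}

#' Ordinary kriging of a shipboard oceanographic field
#'
#' Interpolates sampled surface values (SST, SSS or SSF) onto a prediction
#' grid by ordinary kriging: the weights of each prediction sum to one,
#' and with a zero nugget the surface honours the samples exactly. A
#' first-order polynomial trend is optionally removed first ("detrending")
#' when its overall F-test is significant; the variogram is an exponential
#' model fit by weighted least squares unless supplied.
#'
#' @param samples data.frame `x`, `y`, `value` of located samples (>= 5).
#' @param grid data.frame of prediction cells with `x`, `y` (and
#'   optionally `cell_id`).
#' @param variogram optional list `nugget`, `psill`, `range`; fitted from
#'   the samples when `NULL`.
#' @param detrend `"auto"` removes a first-order trend when its F-test
#'   p < 0.05; `"never"` and `"always"` force the choice.
#' @param variable label for the interpolated field.
#' @param cruise optional cruise identifier carried in the result.
#' @return object of class `env_surface`: data.frame `cell_id`, `x`, `y`,
#'   `value`, `se`, with attributes `mean_se`, `variogram`, `detrended`,
#'   `variable`, `cruise`.
#' @export
krige_surface <- function(samples, grid, variogram = NULL,
                          detrend = c("auto", "never", "always"),
                          variable = "sst", cruise = NA) {
  detrend <- match.arg(detrend)
  stopifnot(is.data.frame(samples), all(c("x", "y", "value") %in% names(samples)),
            is.data.frame(grid), all(c("x", "y") %in% names(grid)))
  if (nrow(samples) < 5L) {
    stop("ordinary kriging requires >= 5 sample points", call. = FALSE)
  }
  # duplicate locations: identical values collapse, conflicting values error
  key <- paste(signif(samples$x, 10), signif(samples$y, 10))
  if (anyDuplicated(key)) {
    rng <- tapply(samples$value, key, function(v) diff(range(v)))
    if (any(rng > 1e-9)) {
      stop("duplicate sample locations with conflicting values", call. = FALSE)
    }
    samples <- samples[!duplicated(key), , drop = FALSE]
  }

  z <- samples$value
  trend_fit <- NULL
  use_trend <- FALSE
  if (detrend != "never") {
    trend_fit <- stats::lm(value ~ x + y, data = samples)
    fstat <- summary(trend_fit)$fstatistic
    p_trend <- if (is.null(fstat)) 1 else
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    use_trend <- detrend == "always" || p_trend < 0.05
  }
  if (use_trend) z <- stats::residuals(trend_fit)

  if (is.null(variogram)) {
    variogram <- fit_variogram(empirical_variogram(samples$x, samples$y, z))
  }
  stopifnot(variogram$psill > 0, variogram$range > 0, variogram$nugget >= 0)

  n <- nrow(samples)
  D <- as.matrix(stats::dist(cbind(samples$x, samples$y)))
  G <- expo_semivariance(D, variogram$nugget, variogram$psill, variogram$range)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(samples$x, grid$x, "-")^2 + outer(samples$y, grid$y, "-")^2)
  B <- rbind(expo_semivariance(d0, variogram$nugget, variogram$psill,
                               variogram$range),
             rep(1, nrow(grid)))
  W <- tryCatch(solve(A, B), error = function(e) {
    stop("singular kriging system (n = ", n, ", range = ",
         signif(variogram$range, 4), "): ", conditionMessage(e),
         call. = FALSE)
  })
  pred <- drop(crossprod(W[seq_len(n), , drop = FALSE], z))
  kvar <- colSums(W * B)
  if (use_trend) {
    pred <- pred + stats::predict(trend_fit, newdata = grid)
  }
  out <- data.frame(
    cell_id = if (!is.null(grid$cell_id)) grid$cell_id else seq_len(nrow(grid)),
    x = grid$x, y = grid$y,
    value = pred,
    se = sqrt(pmax(kvar, 0))
  )
  structure(out,
            class = c("env_surface", "data.frame"),
            mean_se = mean(out$se),
            variogram = variogram,
            detrended = use_trend,
            variable = variable,
            cruise = cruise)
}

#' Quality-filter a batch of kriged surfaces
#'
#' A surface is rejected when its average kriging standard error lies more
#' than three standard deviations from the mean of all surfaces' average
#' standard errors.
#'
#' @param surfaces list of `env_surface` objects (>= 2), or a numeric
#'   vector of mean standard errors.
#' @return list with `accepted` and `rejected` index vectors, plus a
#'   `summary` data.frame of mean standard errors.
#' @export
filter_surfaces <- function(surfaces) {
  mean_se <- if (is.numeric(surfaces)) {
    surfaces
  } else {
    vapply(surfaces, function(s) attr(s, "mean_se"), numeric(1))
  }
  if (length(mean_se) < 2L) {
    stop("at least 2 surfaces are required (SD undefined otherwise)",
         call. = FALSE)
  }
  m <- mean(mean_se)
  s <- stats::sd(mean_se)
  rejected <- which(abs(mean_se - m) > 3 * s)
  list(
    accepted = setdiff(seq_along(mean_se), rejected),
    rejected = rejected,
    summary = data.frame(surface = seq_along(mean_se), mean_se = mean_se,
                         rejected = seq_along(mean_se) %in% rejected)
  )
}

#' Fill missing underway (TSG) surface values from CTD casts
#'
#' Regresses underway thermosalinograph values on co-located CTD values
#' while controlling for month (linear) and year (categorical), then
#' predicts the missing underway records from the nearest CTD cast within
#' a 3-km radius. Gaps with no CTD value inside the radius are flagged
#' unfillable, never silently imputed.
#'
#' @param tsg data.frame `x`, `y`, `month`, `year`, `value` with `NA`
#'   values marking gaps.
#' @param ctd data.frame `x`, `y`, `month`, `year`, `value` of CTD-derived
#'   surface values.
#' @param max_radius_km maximum TSG-CTD pairing distance (km).
#' @return list: `predictions` (`tsg` rows for gaps, with `fill` and
#'   `fillable` columns), `r_squared` of the calibration regression, and
#'   the fitted `model`.
#' @export
fill_missing_tsg <- function(tsg, ctd, max_radius_km = 3) {
  need <- c("x", "y", "month", "year", "value")
  stopifnot(all(need %in% names(tsg)), all(need %in% names(ctd)))
  nearest_ctd <- function(rows) {
    idx <- integer(nrow(rows)); dist <- numeric(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      same <- which(ctd$year == rows$year[i] & ctd$month == rows$month[i])
      if (length(same) == 0L) { idx[i] <- NA_integer_; dist[i] <- Inf; next }
      dd <- sqrt((ctd$x[same] - rows$x[i])^2 + (ctd$y[same] - rows$y[i])^2)
      j <- which.min(dd)
      idx[i] <- same[j]; dist[i] <- dd[j]
    }
    list(idx = idx, dist = dist)
  }
  obs <- tsg[!is.na(tsg$value), , drop = FALSE]
  gap <- tsg[is.na(tsg$value), , drop = FALSE]
  if (nrow(obs) < 5L) stop("too few observed TSG records to calibrate",
                           call. = FALSE)
  mo <- nearest_ctd(obs)
  train <- obs[is.finite(mo$dist) & mo$dist <= max_radius_km, , drop = FALSE]
  train$ctd_value <- ctd$value[mo$idx[is.finite(mo$dist) &
                                        mo$dist <= max_radius_km]]
  if (nrow(train) < 5L) stop("too few TSG records pair with a CTD value",
                             call. = FALSE)
  multi_year <- length(unique(train$year)) > 1L
  fml <- if (multi_year) value ~ ctd_value + month + factor(year)
         else value ~ ctd_value + month
  fit <- stats::lm(fml, data = train)
  r2 <- summary(fit)$r.squared

  if (nrow(gap) > 0L) {
    mg <- nearest_ctd(gap)
    gap$fillable <- is.finite(mg$dist) & mg$dist <= max_radius_km
    if (multi_year) {
      gap$fillable <- gap$fillable & gap$year %in% unique(train$year)
    }
    gap$ctd_value <- NA_real_
    gap$ctd_value[gap$fillable] <- ctd$value[mg$idx[gap$fillable]]
    gap$fill <- NA_real_
    if (any(gap$fillable)) {
      gap$fill[gap$fillable] <-
        stats::predict(fit, newdata = gap[gap$fillable, , drop = FALSE])
    }
  } else {
    gap$fillable <- logical(0)
    gap$ctd_value <- numeric(0)
    gap$fill <- numeric(0)
  }
  list(predictions = gap, r_squared = r2, model = fit)
}
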