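#' Default per-bin covariate specifications
#'
#' Mean, SD and range targets for every survey-bin covariate, matching the
#' summary statistics of the ACCESS-style strip-survey dataset the package
#' emulates: shipboard oceanography (fluorescence, salinity, temperature),
#' bathymetric and distance covariates, monthly climate indices (UI, NPGO,
#' PDO, SOI) and the observation-condition ("detection") variables used in
#' zero-inflation components. Time of day is carried in decimal hours.
#'
#' @return data.frame with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
default_covariate_specs <- function() {
  specs <- rbind(
    c("ssf",            2.5,   6.7,  -8.6,   28.1),
    c("sss",           33.4,   0.36, 29.7,   34.1),
    c("sst",           12.3,   1.7,   8.2,   16.4),
    c("dist_cordell",  37.6,  24.9,   0.8,  115.5),
    c("dist_200m",     11.6,  10.3,   0.02,  47.3),
    c("depth",        179.2, 240.0,   7.6, 2075.6),
    c("contour_index",  0.2,   0.2,   0,      1),
    c("dist_mainland", 26.5,  10.5,   1.2,   50.5),
    c("dist_island",   25.9,  16.4,   0.1,   89.4),
    c("ui",           183.7,  71.3,  46,    339.5),
    c("npgo",           0.6,   0.9,  -1.7,    2.1),
    c("pdo",           -0.4,   1.0,  -2.2,    1.9),
    c("soi",            0.4,   1.6,  -2.7,    4.3),
    c("sea_state",      2.8,   1.4,   0,      6),
    c("swell",          1.8,   4.0,   0,      8),
    c("visibility",     5.3,   2.0,   0,      6),
    c("cloud_cover",    4.7,   3.4,   0,      9),
    c("time_of_day",   12.32,  3.0,   6.13,  20.08)
  )
  out <- data.frame(
    variable = specs[, 1],
    mean = as.numeric(specs[, 2]),
    sd = as.numeric(specs[, 3]),
    min = as.numeric(specs[, 4]),
    max = as.numeric(specs[, 5]),
    stringsAsFactors = FALSE
  )
  out
}

#' Simulation configuration for synthetic strip surveys
#'
#' Defines the study conditions the generators emulate: 37 cruises over
#' April-October 2004-2013, roughly 110 three-km bins per cruise (about
#' 4,070 bins in total), vessel-dependent strip widths of 100/200/300 m,
#' and covariates matching [default_covariate_specs()]. Geometry is planar
#' Cartesian in kilometres; transects are parallel cross-shelf lines 10 km
#' apart.
#'
#' @param n_cruises number of cruises.
#' @param months integer cruise months, subset of 4..10 (April-October).
#' @param years integer survey years.
#' @param bins_per_cruise number of 3-km bins surveyed per cruise.
#' @param grid_dims integer `(rows, cols)` of the 1-km^2 prediction grid.
#' @param vessel_strip_widths_m candidate strip widths in metres.
#' @param covariate_specs data.frame as from [default_covariate_specs()];
#'   every `sd` must be positive and `min < max`.
#' @param transect_spacing_km spacing between parallel transect lines.
#' @param bins_per_line bins laid along each transect line.
#' @param climate_phi lag-1 autocorrelation of the monthly climate series.
#' @param seed integer seed; fully determines all generated output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cruises = 37L,
                       months = 4:10,
                       years = 2004:2013,
                       bins_per_cruise = 110L,
                       grid_dims = c(60L, 78L),
                       vessel_strip_widths_m = c(100, 200, 300),
                       covariate_specs = default_covariate_specs(),
                       transect_spacing_km = 10,
                       bins_per_line = 20L,
                       climate_phi = 0.5,
                       seed = 1L) {
  if (length(months) == 0L || length(years) == 0L) {
    stop("`months` and `years` must be non-empty", call. = FALSE)
  }
  if (!all(months %in% 4:10)) {
    stop("`months` must be a subset of 4..10", call. = FALSE)
  }
  stopifnot(
    n_cruises >= 1L, bins_per_cruise >= 0L,
    length(grid_dims) == 2L, all(grid_dims >= 1L),
    all(vessel_strip_widths_m > 0),
    is.data.frame(covariate_specs),
    all(c("variable", "mean", "sd", "min", "max") %in%
          names(covariate_specs))
  )
  if (any(covariate_specs$sd <= 0)) {
    stop("all covariate sds must be > 0", call. = FALSE)
  }
  if (any(covariate_specs$min >= covariate_specs$max)) {
    stop("covariate min must be < max", call. = FALSE)
  }
  structure(
    list(
      n_cruises = as.integer(n_cruises),
      months = sort(unique(as.integer(months))),
      years = sort(unique(as.integer(years))),
      bins_per_cruise = as.integer(bins_per_cruise),
      grid_dims = as.integer(grid_dims),
      vessel_strip_widths_m = sort(vessel_strip_widths_m),
      covariate_specs = covariate_specs,
      transect_spacing_km = transect_spacing_km,
      bins_per_line = as.integer(bins_per_line),
      climate_phi = climate_phi,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

spec_row <- function(config, variable) {
  sp <- config$covariate_specs
  row <- sp[sp$variable == variable, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no covariate spec for '", variable, "'", call. = FALSE)
  }
  row
}

draw_covariate <- function(config, variable, n) {
  row <- spec_row(config, variable)
  rtrunc_norm(n, row$mean, row$sd, row$min, row$max)
}

# Deterministic cross-shelf depth profile: a gentle shelf ramp over the
# inner 85% of the offshore axis, then an exponential drop down the slope.
# Yields a right-skewed depth distribution with mean near 180 m and the
# 200-m isobath at a fixed offshore position, so distance-to-isobath
# covariates are geometrically consistent with depth.
shelf_depth <- function(u, d_min = 7.6, d_break = 200, d_max = 2075.6,
                        shelf_frac = 0.85) {
  stopifnot(all(u >= 0 & u <= 1))
  on_shelf <- u <= shelf_frac
  d <- numeric(length(u))
  d[on_shelf] <- d_min + (d_break - d_min) * (u[on_shelf] / shelf_frac)
  v <- (u[!on_shelf] - shelf_frac) / (1 - shelf_frac)
  d[!on_shelf] <- d_break * (d_max / d_break)^v
  d
}

#' Generate a synthetic table of 3-km survey bins
#'
#' Lays bins along parallel cross-shelf transect lines, assigns each cruise
#' a month/year and a vessel (hence a strip width, so bin area = width x
#' 3 km), draws covariates from truncated normals matching their
#' configured mean/SD/range, derives depth from a smooth cross-shelf
#' gradient (and distance to the 200-m isobath from that same geometry),
#' and attaches monthly climate-index values at lags 0-3 from a seeded
#' AR(1) series.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per bin per cruise. Columns include bin
#'   coordinates (`x_km`, `y_km`), `cruise`, `year`, `month`, `area_km2`,
#'   all covariates of [default_covariate_specs()], and lagged climate
#'   columns `<index>_lag0` .. `<index>_lag3`.
#' @export
generate_survey_bins <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_cruises <- config$n_cruises
    npc <- config$bins_per_cruise
    if (npc == 0L) {
      return(empty_bins())
    }
    # cruise calendar: spread cruises over years, months drawn per cruise
    year <- config$years[((seq_len(n_cruises) - 1L) %% length(config$years)) + 1L]
    month <- sample(config$months, n_cruises, replace = TRUE)
    vessel <- sample(seq_along(config$vessel_strip_widths_m), n_cruises,
                     replace = TRUE)
    width_km <- config$vessel_strip_widths_m[vessel] / 1000

    # fixed survey design: same transect layout every cruise
    n_lines <- ceiling(npc / config$bins_per_line)
    line_of_bin <- rep(seq_len(n_lines), each = config$bins_per_line)[seq_len(npc)]
    pos_on_line <- ((seq_len(npc) - 1L) %% config$bins_per_line) + 1L
    x_km <- (pos_on_line - 0.5) * 3
    y_km <- (line_of_bin - 1) * config$transect_spacing_km
    x_max <- max(x_km) + 1.5

    climate <- generate_climate_series(config, phi = config$climate_phi,
                                       seed = config$seed + 1L)

    rows <- vector("list", n_cruises)
    for (cr in seq_len(n_cruises)) {
      u <- x_km / x_max
      depth_det <- shelf_depth(u)
      depth <- depth_det * exp(stats::rnorm(npc, 0, 0.15))
      dsp <- spec_row(config, "depth")
      depth <- pmin(pmax(depth, dsp$min), dsp$max)
      # 200-m isobath sits at the end of the shelf ramp
      x200 <- 0.85 * x_max
      d200sp <- spec_row(config, "dist_200m")
      dist_200m <- pmin(pmax(abs(x_km - x200), d200sp$min), d200sp$max)
      d <- data.frame(
        cruise = cr,
        year = year[cr],
        month = month[cr],
        bin = seq_len(npc),
        x_km = x_km,
        y_km = y_km,
        strip_width_m = width_km[cr] * 1000,
        area_km2 = width_km[cr] * 3,
        depth = depth,
        dist_200m = dist_200m
      )
      for (v in c("ssf", "sss", "sst", "dist_cordell", "contour_index",
                  "dist_mainland", "dist_island", "sea_state", "swell",
                  "visibility", "cloud_cover", "time_of_day")) {
        d[[v]] <- draw_covariate(config, v, npc)
      }
      rows[[cr]] <- d
    }
    bins <- do.call(rbind, rows)
    attach_climate_lags(bins, climate)
  })
}

empty_bins <- function() {
  cols <- c("cruise", "year", "month", "bin", "x_km", "y_km",
            "strip_width_m", "area_km2", "depth", "dist_200m", "ssf", "sss",
            "sst", "dist_cordell", "contour_index", "dist_mainland",
            "dist_island", "sea_state", "swell", "visibility", "cloud_cover",
            "time_of_day")
  out <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(cols)))
  names(out) <- cols
  out
}

#' Generate the 1-km^2 prediction grid
#'
#' Cell centroids on a regular 1-km lattice carrying the static covariates
#' (depth and the distance/bathymetric set) consistent with the same
#' cross-shelf geometry as [generate_survey_bins()]; oceanographic values
#' are drawn from their covariate specs so models can be projected onto
#' the grid for any month/year.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per cell: `cell_id`, `row`, `col`,
#'   `x_km`, `y_km` and covariate columns.
#' @export
generate_prediction_grid <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    nr <- config$grid_dims[1]
    nc <- config$grid_dims[2]
    g <- expand.grid(col = seq_len(nc), row = seq_len(nr))
    g <- g[, c("row", "col")]
    g$cell_id <- seq_len(nrow(g))
    g$x_km <- g$col - 0.5
    g$y_km <- g$row - 0.5
    u <- g$x_km / nc
    dsp <- spec_row(config, "depth")
    g$depth <- pmin(pmax(shelf_depth(u) * exp(stats::rnorm(nrow(g), 0, 0.1)),
                         dsp$min), dsp$max)
    d200sp <- spec_row(config, "dist_200m")
    g$dist_200m <- pmin(pmax(abs(g$x_km - 0.85 * nc), d200sp$min), d200sp$max)
    for (v in c("ssf", "sss", "sst", "dist_cordell", "contour_index",
                "dist_mainland", "dist_island")) {
      g[[v]] <- draw_covariate(config, v, nrow(g))
    }
    g[, c("cell_id", "row", "col", "x_km", "y_km", "depth", "dist_200m",
          "ssf", "sss", "sst", "dist_cordell", "contour_index",
          "dist_mainland", "dist_island")]
  })
}

#' Define the generating count model for synthetic counts
#'
#' @param family `"NB"` or `"ZINB"`.
#' @param coefficients named numeric vector for the count component (log
#'   link); names must be covariate columns, plus `"(Intercept)"`.
#' @param inflation_coefficients named numeric vector for the structural
#'   zero component (logit link); ZINB only.
#' @param alpha positive over-dispersion (NB2 variance mu + alpha mu^2);
#'   values below 1e-8 are treated as the Poisson limit.
#' @return object of class `true_model`.
#' @export
true_model <- function(family = c("NB", "ZINB"),
                       coefficients,
                       inflation_coefficients = NULL,
                       alpha = 1) {
  family <- match.arg(family)
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            alpha >= 0)
  if (family == "NB" && length(inflation_coefficients) > 0L) {
    stop("NB family must have empty inflation_coefficients", call. = FALSE)
  }
  if (family == "ZINB" &&
      (is.null(inflation_coefficients) ||
       is.null(names(inflation_coefficients)))) {
    stop("ZINB requires named inflation_coefficients", call. = FALSE)
  }
  structure(
    list(family = family, coefficients = coefficients,
         inflation_coefficients = inflation_coefficients, alpha = alpha,
         offset_rule = "ln(bin area)"),
    class = "true_model"
  )
}

linpred <- function(coefs, data) {
  eta <- rep(0, nrow(data))
  for (nm in names(coefs)) {
    if (nm == "(Intercept)") {
      eta <- eta + coefs[[nm]]
    } else {
      if (is.null(data[[nm]])) {
        stop("coefficient '", nm, "' has no matching covariate column",
             call. = FALSE)
      }
      eta <- eta + coefs[[nm]] * data[[nm]]
    }
  }
  eta
}

#' Draw counts from a generating NB or ZINB model
#'
#' Counts are NB2 with mean `exp(X beta + ln area)` and over-dispersion
#' `alpha`; under ZINB an independent structural zero occurs with
#' probability `plogis(Z gamma)`.
#'
#' @param bins survey-bin table from [generate_survey_bins()]; must carry
#'   every covariate named in `truth` and positive `area_km2`.
#' @param truth a [true_model()].
#' @param seed integer seed.
#' @param response name of the count column to fill.
#' @return `bins` with the count column added.
#' @export
generate_counts <- function(bins, truth, seed, response = "count") {
  stopifnot(inherits(truth, "true_model"), is.data.frame(bins))
  if (nrow(bins) == 0L) {
    bins[[response]] <- integer(0)
    return(bins)
  }
  if (any(bins$area_km2 <= 0)) stop("offsets must be positive", call. = FALSE)
  with_seed(seed, {
    mu <- exp(linpred(truth$coefficients, bins) + log(bins$area_km2))
    y <- if (truth$alpha < 1e-8) {
      stats::rpois(nrow(bins), mu)
    } else {
      stats::rnbinom(nrow(bins), mu = mu, size = 1 / truth$alpha)
    }
    if (truth$family == "ZINB") {
      p0 <- stats::plogis(linpred(truth$inflation_coefficients, bins))
      y[stats::runif(nrow(bins)) < p0] <- 0L
    }
    bins[[response]] <- as.integer(y)
    bins
  })
}

#' Generate monthly climate-index series
#'
#' Stationary AR(1) series for NPGO, PDO, SOI and UI, location/scale
#' matched to each index's covariate spec and kept inside its range by
#' innovation resampling (so the UI stays strictly positive). The series
#' starts at least 3 months before the first cruise month so lags 0-3 are
#' always available.
#'
#' @param config a [sim_config()].
#' @param phi lag-1 autocorrelation, in `[0, 1)`.
#' @param seed integer seed.
#' @return data.frame `year`, `month`, `npgo`, `pdo`, `soi`, `ui`.
#' @export
generate_climate_series <- function(config, phi = 0.5, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (phi < 0 || phi >= 1) stop("phi must be in [0, 1)", call. = FALSE)
  with_seed(seed, {
    y0 <- min(config$years)
    y1 <- max(config$years)
    m0 <- min(config$months)
    # extend >= 3 months before the first cruise month
    start <- 12L * y0 + (m0 - 1L) - 4L
    end <- 12L * y1 + 11L
    tt <- start:end
    n <- length(tt)
    out <- data.frame(year = tt %/% 12L, month = tt %% 12L + 1L)
    for (v in c("npgo", "pdo", "soi", "ui")) {
      row <- spec_row(config, v)
      lo <- (row$min - row$mean) / row$sd
      hi <- (row$max - row$mean) / row$sd
      z <- numeric(n)
      z[1] <- rtrunc_norm(1, 0, 1, lo, hi)
      innov_sd <- sqrt(max(1 - phi^2, 1e-12))
      for (i in seq_len(n - 1L)) {
        m <- phi * z[i]
        z[i + 1L] <- if (innov_sd < 1e-6) {
          min(max(m, lo), hi)
        } else {
          rtrunc_norm(1, m, innov_sd, lo, hi)
        }
      }
      out[[v]] <- row$mean + row$sd * z
    }
    out
  })
}

#' Attach lagged climate columns to a bin or grid table
#'
#' Adds `<index>_lag0` .. `<index>_lag3` columns by matching each row's
#' `year`/`month` against the climate series at the corresponding lag.
#'
#' @param data table with `year` and `month` columns.
#' @param climate series from [generate_climate_series()].
#' @param lags integer lags to attach.
#' @return `data` with lag columns added.
#' @export
attach_climate_lags <- function(data, climate, lags = 0:3) {
  stopifnot(all(c("year", "month") %in% names(data)))
  for (lag in lags) {
    lagged <- lag_series(climate, lag)
    key_d <- 12L * data$year + (data$month - 1L)
    key_c <- 12L * lagged$year + (lagged$month - 1L)
    idx <- match(key_d, key_c)
    if (anyNA(idx) && nrow(data) > 0L) {
      stop("climate series does not cover all survey months at lag ", lag,
           call. = FALSE)
    }
    for (v in c("npgo", "pdo", "soi", "ui")) {
      data[[paste0(v, "_lag", lag)]] <- lagged[[v]][idx]
    }
  }
  data
}
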