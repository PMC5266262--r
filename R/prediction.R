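#' Project a fitted count model onto the prediction grid
#'
#' Predicts the expected foraging count per 1-km^2 cell for a given
#' month/year at the reference offset `ln(1 km^2)` (ZINB: conditional
#' mean times one minus the structural-zero probability). Cells whose
#' covariates fall outside the training envelope of any model covariate
#' are flagged as extrapolations.
#'
#' @param model a `count_fit`.
#' @param grid prediction-grid table carrying every covariate column the
#'   model uses, plus `x_km`/`y_km` (or `x`/`y`) coordinates.
#' @param month,year the scope of the surface.
#' @param species optional species label.
#' @return object of class `abundance_surface`: data.frame `cell_id`,
#'   `x`, `y`, `abundance`, `extrapolated`, with attributes `species`,
#'   `month`, `year`.
#' @export
predict_surface <- function(model, grid, month, year, species = NA) {
  stopifnot(inherits(model, "count_fit"), is.data.frame(grid))
  nd <- grid
  nd$month <- month
  nd$year <- year
  nd[[model$offset_var]] <- 1
  if (!is.null(model$xlevels$year) &&
      !(year %in% model$xlevels$year) &&
      length(model$xlevels$year) > 1L) {
    stop("year ", year, " was not in the training data", call. = FALSE)
  }
  cols <- unique(vapply(c(model$terms, model$inflation_terms), term_column,
                        character(1)))
  missing <- setdiff(cols, names(nd))
  if (length(missing) > 0L) {
    stop("grid is missing covariate column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- if (!is.null(grid$x_km)) grid$x_km else grid$x
  y <- if (!is.null(grid$y_km)) grid$y_km else grid$y
  if (is.null(x) || is.null(y)) {
    stop("grid must carry x/y (or x_km/y_km) coordinates", call. = FALSE)
  }
  pred <- stats::predict(model, newdata = nd, type = "response")
  extrap <- rep(FALSE, nrow(nd))
  for (cn in cols) {
    rg <- model$training_ranges[[cn]]
    if (!is.null(rg)) {
      extrap <- extrap | nd[[cn]] < rg[1] | nd[[cn]] > rg[2]
    }
  }
  out <- data.frame(
    cell_id = if (!is.null(grid$cell_id)) grid$cell_id else seq_len(nrow(grid)),
    x = x, y = y,
    abundance = pred,
    extrapolated = extrap
  )
  structure(out, class = c("abundance_surface", "data.frame"),
            species = species, month = month, year = year)
}

#' Construct an abundance surface from raw values
#'
#' Mainly for tests and composites built from external predictions.
#'
#' @param abundance nonnegative per-cell values.
#' @param x,y cell centroid coordinates (defaults: unit lattice order).
#' @param species,month,year scope labels.
#' @return an `abundance_surface`.
#' @export
abundance_surface <- function(abundance, x = NULL, y = NULL, species = NA,
                              month = NA, year = NA) {
  n <- length(abundance)
  if (is.null(x)) x <- seq_len(n)
  if (is.null(y)) y <- rep(0, n)
  structure(
    data.frame(cell_id = seq_len(n), x = x, y = y, abundance = abundance,
               extrapolated = FALSE),
    class = c("abundance_surface", "data.frame"),
    species = species, month = month, year = year
  )
}

#' Standardize an abundance surface
#'
#' Computes the per-cell z-score of log abundance,
#' `z_i = (log(x_i + 1) - mu) / sigma`, with `mu` and `sigma` the mean and
#' population standard deviation of `log(x + 1)` over the surface's own
#' cells, then a percent rank in `[0, 100]` for high- to low-use display.
#'
#' @param surface an `abundance_surface` (>= 2 cells).
#' @return the surface with `z` and `pct_rank` columns added.
#' @export
standardize_abundance <- function(surface) {
  stopifnot(is.data.frame(surface), "abundance" %in% names(surface),
            nrow(surface) >= 2L)
  lx <- log(surface$abundance + 1)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma <= 0) {
    stop("constant surface: standardization undefined (sigma = 0)",
         call. = FALSE)
  }
  surface$z <- (lx - mu) / sigma
  surface$pct_rank <- percent_rank(surface$z)
  surface
}

#' Peak foraging months per species
#'
#' The top three months of greatest predicted abundance used for annual
#' and composite maps: May/June/July for the black-footed albatross,
#' June/July/September for the fulmar and both shearwaters,
#' July/September/October for both phalaropes.
#'
#' @return named list of integer month vectors.
#' @export
peak_months <- function() {
  list(
    black_footed_albatross = c(5L, 6L, 7L),
    northern_fulmar = c(6L, 7L, 9L),
    pink_footed_shearwater = c(6L, 7L, 9L),
    sooty_shearwater = c(6L, 7L, 9L),
    red_phalarope = c(7L, 9L, 10L),
    red_necked_phalarope = c(7L, 9L, 10L)
  )
}

#' Multi-species composite foraging map
#'
#' For each species, standardized values are averaged across its surfaces
#' from the top three peak months (over all years supplied); the
#' composite is the across-species mean of those species-standardized
#' surfaces, percent-ranked, with the upper 50 percent flagged as the
#' highest-use display mask.
#'
#' @param surfaces named list (by species) of lists of
#'   `abundance_surface` objects carrying `month` attributes.
#' @param top_months named list mapping each species to its three peak
#'   months; defaults to [peak_months()].
#' @return data.frame `cell_id`, `x`, `y`, `z`, `pct_rank`, `top50`, plus
#'   a `species_z` attribute with the per-species mean-z matrix.
#' @export
composite_map <- function(surfaces, top_months = peak_months()) {
  stopifnot(is.list(surfaces), length(surfaces) >= 1L,
            !is.null(names(surfaces)))
  species <- names(surfaces)
  zmat <- NULL
  ref <- NULL
  for (sp in species) {
    months <- top_months[[sp]]
    if (is.null(months)) {
      stop("no peak months configured for species '", sp, "'",
           call. = FALSE)
    }
    surfs <- surfaces[[sp]]
    if (inherits(surfs, "abundance_surface")) surfs <- list(surfs)
    use <- Filter(function(s) {
      m <- attr(s, "month")
      is.na(m) || m %in% months
    }, surfs)
    if (length(use) == 0L) {
      stop("species '", sp, "' has no surfaces in its peak months",
           call. = FALSE)
    }
    zs <- lapply(use, function(s) {
      if (is.null(s$z)) s <- standardize_abundance(s)
      if (is.null(ref)) {
        ref <<- s[, c("cell_id", "x", "y")]
      } else if (!identical(s$cell_id, ref$cell_id)) {
        stop("surfaces are not on a common cell set", call. = FALSE)
      }
      s$z
    })
    zsp <- Reduce(`+`, zs) / length(zs)
    zmat <- cbind(zmat, zsp)
  }
  colnames(zmat) <- species
  z <- rowMeans(zmat)
  out <- data.frame(cell_id = ref$cell_id, x = ref$x, y = ref$y, z = z)
  out$pct_rank <- percent_rank(z)
  out$top50 <- out$pct_rank >= 50
  attr(out, "species_z") <- zmat
  out
}

#' Marginal-effect profile of one covariate
#'
#' Sets the focal variable to each value of `values` for every
#' observation, holds all other covariates at their observed values,
#' and averages the model's predicted counts; the standard error is by
#' the delta method over the model's estimated coefficients. A variable
#' absent from the model yields a flat profile.
#'
#' @param model a `count_fit`.
#' @param variable focal data column (e.g. `"sst"`, `"pdo_lag3"`).
#' @param values sequence of focal-variable values to profile.
#' @param data observation data over which predictions are averaged.
#' @return data.frame `value`, `estimate`, `se`.
#' @export
marginal_effect_profile <- function(model, variable, values, data) {
  stopifnot(inherits(model, "count_fit"), variable %in% names(data),
            length(values) >= 1L)
  Vc <- vcov(model, "count")
  Vz <- if (model$family == "zinb") vcov(model, "inflation") else NULL
  est <- se <- numeric(length(values))
  for (i in seq_along(values)) {
    nd <- data
    nd[[variable]] <- values[i]
    pred <- stats::predict(model, newdata = nd, type = "response")
    est[i] <- mean(pred)
    X <- count_design(model, nd)
    if (model$family == "nb") {
      g <- colMeans(pred * X)
      se[i] <- sqrt(drop(t(g) %*% Vc %*% g))
    } else {
      mu <- stats::predict(model, newdata = nd, type = "count")
      pz <- stats::predict(model, newdata = nd, type = "zprob")
      Z <- inflation_design(model, nd)
      gb <- colMeans((1 - pz) * mu * X)
      gg <- colMeans(-pz * (1 - pz) * mu * Z)
      se[i] <- sqrt(drop(t(gb) %*% Vc %*% gb) + drop(t(gg) %*% Vz %*% gg))
    }
  }
  data.frame(value = values, estimate = est, se = se)
}

# count-component model matrix on new data, aligned to coefficient order
count_design <- function(model, nd) {
  rhs <- unlist(lapply(model$terms, term_rhs), use.names = FALSE)
  if (model$controls) rhs <- c(rhs, control_rhs_from_levels(model, nd))
  rhs <- c(rhs, model$extra_rhs)
  fml <- if (length(rhs) == 0L) ~1 else stats::reformulate(rhs)
  environment(fml) <- globalenv()
  X <- stats::model.matrix(fml, nd)
  X[, names(model$coefficients), drop = FALSE]
}

inflation_design <- function(model, nd) {
  rhs <- unlist(lapply(model$inflation_terms, term_rhs), use.names = FALSE)
  fml <- if (length(rhs) == 0L) ~1 else stats::reformulate(rhs)
  environment(fml) <- globalenv()
  Z <- stats::model.matrix(fml, nd)
  Z[, names(model$inflation_coefficients), drop = FALSE]
}

control_rhs_from_levels <- function(model, nd) {
  out <- character(0)
  if (any(grepl("^month$", names(model$coefficients))) ||
      any(grepl("I\\(month\\^2\\)", names(model$coefficients)))) {
    out <- c(out, "month", "I(month^2)")
  }
  if (any(grepl("^factor\\(year\\)", names(model$coefficients)))) {
    out <- c(out, "factor(year)")
  }
  out
}
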