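#' Build a minimum-set reserve problem from abundance surfaces
#'
#' Planning units are the 1-km^2 grid cells; the feature amount of a cell
#' for a species is its species-standardized predicted abundance shifted
#' to be nonnegative; each feature's target is the scenario fraction of
#' its total amount. Boundary lengths are 1 km per shared rook edge of
#' the unit cells. Species penalty factors follow IUCN threat status
#' (1 = Least Concern, 2 = Near Threatened, 3 = Vulnerable).
#'
#' @param surfaces named list (by species) of standardized
#'   `abundance_surface` objects (the `z` column is used; surfaces
#'   without one are standardized first) on a common cell set.
#' @param target scenario conservation target fraction(s) in (0, 1];
#'   recycled per feature. The study scenarios are 0.10, 0.30 and 0.50.
#' @param spf per-feature species penalty factor (> 0), recycled.
#' @param blm boundary length modifier (>= 0); the study value is 10.
#' @param cost per-cell cost (default uniform 1).
#' @param n_flips,cooling,cool_every simulated-annealing schedule:
#'   number of single-cell flips, geometric cooling factor applied every
#'   `cool_every` flips.
#' @param n_runs repeated runs for selection frequencies.
#' @return list with `units` (class `planning_units`) and `spec` (class
#'   `reserve_spec`, including per-feature `target_amount` and the
#'   greedy-cover `base_penalty`).
#' @export
build_problem <- function(surfaces, target = 0.3, spf = 1, blm = 10,
                          cost = 1, n_flips = 1e5, cooling = 0.999,
                          cool_every = 100, n_runs = 100) {
  stopifnot(is.list(surfaces), length(surfaces) >= 1L,
            !is.null(names(surfaces)),
            all(target > 0), all(target <= 1), all(spf > 0), blm >= 0)
  ref <- NULL
  amounts <- NULL
  for (sp in names(surfaces)) {
    s <- surfaces[[sp]]
    if (is.null(s$z)) s <- standardize_abundance(s)
    if (is.null(ref)) {
      ref <- s[, c("cell_id", "x", "y")]
    } else if (!identical(s$cell_id, ref$cell_id)) {
      stop("surfaces are not on a common cell set", call. = FALSE)
    }
    a <- s$z - min(s$z)
    if (any(a < 0)) stop("negative feature amount after shift", call. = FALSE)
    amounts <- cbind(amounts, a)
  }
  colnames(amounts) <- names(surfaces)
  n <- nrow(ref)
  nf <- ncol(amounts)
  cost <- rep_len(cost, n)

  # rook neighbours on the unit lattice (1-km shared edges)
  key <- paste(round(ref$x, 6), round(ref$y, 6))
  idx <- stats::setNames(seq_len(n), key)
  nbrs <- lapply(seq_len(n), function(i) {
    cand <- c(paste(round(ref$x[i] + 1, 6), round(ref$y[i], 6)),
              paste(round(ref$x[i] - 1, 6), round(ref$y[i], 6)),
              paste(round(ref$x[i], 6), round(ref$y[i] + 1, 6)),
              paste(round(ref$x[i], 6), round(ref$y[i] - 1, 6)))
    unname(idx[cand[cand %in% names(idx)]])
  })

  units <- structure(
    list(cells = data.frame(cell_id = ref$cell_id, x = ref$x, y = ref$y,
                            cost = cost),
         amounts = amounts, neighbors = nbrs, n = n, n_features = nf),
    class = "planning_units"
  )
  target_amount <- rep_len(target, nf) * colSums(amounts)
  spec <- structure(
    list(features = colnames(amounts),
         target_fraction = rep_len(target, nf),
         target_amount = target_amount,
         spf = rep_len(spf, nf), blm = blm,
         n_flips = n_flips, cooling = cooling, cool_every = cool_every,
         n_runs = n_runs,
         base_penalty = greedy_cover_cost(units, target_amount)),
    class = "reserve_spec"
  )
  list(units = units, spec = spec)
}

#' IUCN-status species penalty factors
#'
#' @param status named character vector of IUCN categories (`"LC"`,
#'   `"NT"`, `"VU"`) per species; defaults to the six study species.
#' @return named numeric vector of penalty factors (LC = 1, NT = 2,
#'   VU = 3).
#' @export
iucn_spf <- function(status = c(black_footed_albatross = "NT",
                                northern_fulmar = "LC",
                                pink_footed_shearwater = "VU",
                                sooty_shearwater = "NT",
                                red_phalarope = "LC",
                                red_necked_phalarope = "LC")) {
  map <- c(LC = 1, NT = 2, VU = 3)
  bad <- setdiff(unique(status), names(map))
  if (length(bad) > 0L) {
    stop("unknown IUCN category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(map[status], names(status))
}

# cost of a greedy target-covering set: repeatedly add the cell with the
# largest total shortfall reduction until every target is met
greedy_cover_cost <- function(units, target_amount) {
  held <- rep(0, length(target_amount))
  sel <- rep(FALSE, units$n)
  cost <- 0
  while (any(held < target_amount - 1e-12)) {
    need <- pmax(target_amount - held, 0)
    gain <- as.numeric(units$amounts %*% pmin(need / pmax(target_amount, 1e-12), 1))
    gain[sel] <- -Inf
    i <- which.max(gain)
    if (!is.finite(gain[i]) || gain[i] <= 0) break
    sel[i] <- TRUE
    held <- held + units$amounts[i, ]
    cost <- cost + units$cells$cost[i]
  }
  max(cost, 1)
}

selected_perimeter <- function(selected, units) {
  if (!any(selected)) return(0)
  sum(vapply(which(selected), function(i) {
    4 - sum(selected[units$neighbors[[i]]])
  }, numeric(1)))
}

#' Minimum-set reserve objective
#'
#' `sum(cost of selected) + blm * exterior boundary length +
#' sum_j spf_j * base_penalty * shortfall_j / target_j`.
#'
#' @param selected logical vector (or cell indices) of selected units.
#' @param units `planning_units`.
#' @param spec `reserve_spec`.
#' @return scalar objective value.
#' @export
reserve_objective <- function(selected, units, spec) {
  sel <- to_logical(selected, units$n)
  held <- held_amounts(sel, units)
  shortfall <- pmax(spec$target_amount - held, 0)
  sum(units$cells$cost[sel]) +
    spec$blm * selected_perimeter(sel, units) +
    sum(spec$spf * spec$base_penalty *
          shortfall / pmax(spec$target_amount, 1e-12))
}

to_logical <- function(selected, n) {
  if (is.logical(selected)) {
    stopifnot(length(selected) == n)
    selected
  } else {
    sel <- rep(FALSE, n)
    sel[selected] <- TRUE
    sel
  }
}

held_amounts <- function(sel, units) {
  if (!any(sel)) return(rep(0, units$n_features))
  colSums(units$amounts[sel, , drop = FALSE])
}

# objective change from flipping cell i (penalty + cost + boundary terms)
flip_delta <- function(i, sel, held, units, spec) {
  sgn <- if (sel[i]) -1 else 1
  new_held <- held + sgn * units$amounts[i, ]
  pen_old <- sum(spec$spf * spec$base_penalty *
                   pmax(spec$target_amount - held, 0) /
                   pmax(spec$target_amount, 1e-12))
  pen_new <- sum(spec$spf * spec$base_penalty *
                   pmax(spec$target_amount - new_held, 0) /
                   pmax(spec$target_amount, 1e-12))
  nb_sel <- sum(sel[units$neighbors[[i]]])
  d_perim <- sgn * (4 - 2 * nb_sel)
  sgn * units$cells$cost[i] + spec$blm * d_perim + (pen_new - pen_old)
}

#' Simulated-annealing minimum-set solver
#'
#' Single-cell-flip simulated annealing with geometric cooling (initial
#' temperature from the SD of objective changes over 1,000 random
#' flips), followed by greedy improvement until no single flip lowers
#' the objective. Deterministic given the seed.
#'
#' @param units `planning_units`.
#' @param spec `reserve_spec`.
#' @param seed integer seed.
#' @return object of class `reserve_solution`: `selected` (cell ids),
#'   `objective`, `held`, `shortfall`, `boundary_length`, `n_selected`.
#' @export
anneal_minset <- function(units, spec, seed = 1L) {
  infeasible <- spec$target_amount > colSums(units$amounts) + 1e-9
  if (any(infeasible)) {
    stop("infeasible target for feature(s): ",
         paste(spec$features[infeasible], collapse = ", "), call. = FALSE)
  }
  n <- units$n
  with_seed(seed, {
    sel <- rep(FALSE, n)
    held <- rep(0, units$n_features)

    # initial temperature: dispersion of deltas along a random flip walk
    deltas <- numeric(1000)
    s2 <- sel; h2 <- held
    for (k in seq_len(1000)) {
      i <- sample.int(n, 1L)
      d <- flip_delta(i, s2, h2, units, spec)
      deltas[k] <- d
      h2 <- h2 + (if (s2[i]) -1 else 1) * units$amounts[i, ]
      s2[i] <- !s2[i]
    }
    t0 <- max(stats::sd(deltas), 1e-6)

    obj <- reserve_objective(sel, units, spec)
    best_sel <- sel; best_obj <- obj
    temp <- t0
    flips <- sample.int(n, spec$n_flips, replace = TRUE)
    accept_u <- stats::runif(spec$n_flips)
    for (k in seq_len(spec$n_flips)) {
      i <- flips[k]
      d <- flip_delta(i, sel, held, units, spec)
      if (d < 0 || accept_u[k] < exp(-d / temp)) {
        held <- held + (if (sel[i]) -1 else 1) * units$amounts[i, ]
        sel[i] <- !sel[i]
        obj <- obj + d
        if (obj < best_obj) { best_obj <- obj; best_sel <- sel }
      }
      if (k %% spec$cool_every == 0L) temp <- temp * spec$cooling
    }

    # greedy polish: monotone descent to a single-flip local optimum
    sel <- best_sel
    held <- held_amounts(sel, units)
    obj <- reserve_objective(sel, units, spec)
    repeat {
      ds <- vapply(seq_len(n), function(i) {
        flip_delta(i, sel, held, units, spec)
      }, numeric(1))
      i <- which.min(ds)
      if (ds[i] >= -1e-10) break
      held <- held + (if (sel[i]) -1 else 1) * units$amounts[i, ]
      sel[i] <- !sel[i]
      obj <- obj + ds[i]
    }

    held <- held_amounts(sel, units)
    structure(
      list(selected = units$cells$cell_id[sel],
           selected_mask = sel,
           objective = reserve_objective(sel, units, spec),
           held = held,
           shortfall = pmax(spec$target_amount - held, 0),
           boundary_length = selected_perimeter(sel, units),
           n_selected = sum(sel),
           spec = spec),
      class = "reserve_solution"
    )
  })
}

#' @export
print.reserve_solution <- function(x, ...) {
  cat(sprintf(
    "Reserve solution: %d cells, objective %.3f, boundary %.0f km\n",
    x$n_selected, x$objective, x$boundary_length))
  met <- x$shortfall <= 1e-9
  cat(sprintf("targets met: %d of %d features\n", sum(met), length(met)))
  invisible(x)
}

#' Selection frequency over repeated optimizations
#'
#' Runs the annealer `n_runs` times with independent seeds, counts how
#' often each cell enters the solution, and converts the counts to a
#' percent rank with the upper 50 percent flagged as the priority
#' display mask.
#'
#' @param units `planning_units`.
#' @param spec `reserve_spec`.
#' @param n_runs number of runs (default from `spec`).
#' @param seed integer master seed.
#' @return object of class `reserve_ensemble`: `frequency` data.frame
#'   (`cell_id`, `x`, `y`, `count`, `pct_rank`, `top50`), `best`
#'   (lowest-objective `reserve_solution`), `objectives`.
#' @export
selection_frequency <- function(units, spec, n_runs = spec$n_runs,
                                seed = 1L) {
  stopifnot(n_runs >= 1)
  seeds <- derive_seeds(seed, n_runs)
  count <- rep(0L, units$n)
  best <- NULL
  objectives <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    sol <- anneal_minset(units, spec, seed = seeds[r])
    count <- count + as.integer(sol$selected_mask)
    objectives[r] <- sol$objective
    if (is.null(best) || sol$objective < best$objective) best <- sol
  }
  freq <- data.frame(cell_id = units$cells$cell_id, x = units$cells$x,
                     y = units$cells$y, count = count)
  freq$pct_rank <- percent_rank(count)
  freq$top50 <- freq$pct_rank >= 50
  structure(
    list(frequency = freq, best = best, objectives = objectives,
         n_runs = n_runs),
    class = "reserve_ensemble"
  )
}
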