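#' Log-normalize a gridded abundance surface
#'
#' Removes the effect of population size before comparing two species'
#' distributions: per-cell weights `p_i = log(x_i + 1) / sum(log(x + 1))`,
#' nonnegative and summing to one. (Log-normalization is deliberately not
#' scale-invariant: doubling all abundances changes `p`.)
#'
#' @param surface an `abundance_surface` or data.frame with `abundance`
#'   and coordinates (>= 2 cells, at least one positive value).
#' @param label optional species label.
#' @return object of class `norm_dist`: data.frame `cell_id`, `x`, `y`,
#'   `p`.
#' @export
log_normalize <- function(surface, label = NA) {
  stopifnot(is.data.frame(surface), "abundance" %in% names(surface),
            nrow(surface) >= 2L)
  if (any(surface$abundance < 0)) {
    stop("abundances must be nonnegative", call. = FALSE)
  }
  lx <- log(surface$abundance + 1)
  s <- sum(lx)
  if (s <= 0) {
    stop("all-zero surface: normalizer is zero", call. = FALSE)
  }
  structure(
    data.frame(cell_id = surface$cell_id, x = surface$x, y = surface$y,
               p = lx / s),
    class = c("norm_dist", "data.frame"),
    label = if (is.na(label)) attr(surface, "species") else label
  )
}

#' Construct a normalized distribution from weights
#'
#' @param p nonnegative weights (rescaled to sum to one).
#' @param x,y cell coordinates.
#' @param label optional label.
#' @return a `norm_dist`.
#' @export
norm_dist <- function(p, x, y, label = NA) {
  stopifnot(length(p) == length(x), length(x) == length(y), all(p >= 0),
            sum(p) > 0)
  structure(
    data.frame(cell_id = seq_along(p), x = x, y = y, p = p / sum(p)),
    class = c("norm_dist", "data.frame"),
    label = label
  )
}

# four cell orderings: lexicographic sweeps starting at each corner of the
# grid's bounding box, alternating the primary sweep axis so separation
# along either coordinate moves the cumulative distributions apart
corner_orders <- function(x, y) {
  list(
    order(y, x),
    order(-y, -x),
    order(x, y),
    order(-x, -y)
  )
}

check_same_cells <- function(d1, d2) {
  if (nrow(d1) != nrow(d2) ||
      !isTRUE(all.equal(d1$x, d2$x)) || !isTRUE(all.equal(d1$y, d2$y))) {
    stop("the two distributions must share an identical cell set",
         call. = FALSE)
  }
}

#' Adapted Cramer-von Mises statistic for two gridded distributions
#'
#' `Psi = sum((Gamma_p1 - Gamma_p2)^2)` where `Gamma` is the cumulative
#' distribution of the normalized per-cell weights along a lexicographic
#' sweep of the grid; the sum is averaged over sweeps starting from each
#' of the four corners of the grid's bounding box (alternating the
#' primary sweep axis), so the statistic depends on neither an arbitrary
#' origin nor a single sweep direction. Psi is 0 iff the distributions
#' are identical.
#'
#' @param d1,d2 `norm_dist` objects on the same cell set.
#' @return nonnegative scalar Psi.
#' @export
cvm_statistic <- function(d1, d2) {
  check_same_cells(d1, d2)
  ords <- corner_orders(d1$x, d1$y)
  psi <- vapply(ords, function(o) {
    sum((cumsum(d1$p[o]) - cumsum(d2$p[o]))^2)
  }, numeric(1))
  mean(psi)
}

#' Randomization test on the adapted Cramer-von Mises statistic
#'
#' The observed Psi is compared against `n_rand` randomizations in which
#' the second species' normalized weights are permuted uniformly across
#' grid cells; `p` is the proportion of random Psi greater than or equal
#' to the observed Psi (so 200 exceedances of 1000 give p = 0.2, and
#' identical inputs give p = 1).
#'
#' @param d1,d2 `norm_dist` objects on the same cell set.
#' @param n_rand number of randomizations (>= 1).
#' @param seed integer seed.
#' @return list `statistic` (observed Psi), `p_value`, `random_stats`.
#' @export
cvm_randomization_test <- function(d1, d2, n_rand = 1000, seed = 1L) {
  if (n_rand < 1) stop("n_rand must be >= 1", call. = FALSE)
  check_same_cells(d1, d2)
  obs <- cvm_statistic(d1, d2)
  ords <- corner_orders(d1$x, d1$y)
  p1_cum <- lapply(ords, function(o) cumsum(d1$p[o]))
  n <- nrow(d1)
  rand <- with_seed(seed, {
    vapply(seq_len(n_rand), function(r) {
      p2p <- d2$p[sample.int(n)]
      mean(vapply(seq_along(ords), function(k) {
        sum((p1_cum[[k]] - cumsum(p2p[ords[[k]]]))^2)
      }, numeric(1)))
    }, numeric(1))
  })
  list(statistic = obs, p_value = exceedance_p(rand, obs),
       random_stats = rand, n_rand = n_rand)
}

# randomization p-value: the proportion of random statistics greater than
# or equal to the observed one (200 exceedances of 1000 give p = 0.2)
exceedance_p <- function(random_stats, observed) {
  mean(random_stats >= observed)
}

#' Generate mock populations with a controlled overlap
#'
#' Builds two normalized distributions on the grid whose overlap
#' coefficient `sum(min(p1, p2))` equals `overlap_fraction` by
#' construction: a shared fraction of mass is placed identically on a
#' central band of cells and the remainder on disjoint offshore/onshore
#' blocks (left block for the first species, right block for the
#' second), with seeded random weight jitter within each block. Used to
#' verify that the randomization test detects populations with little
#' overlap.
#'
#' @param grid data.frame with cell coordinates `x`, `y` (e.g. from
#'   [generate_prediction_grid()]), or an integer to build a square
#'   `grid x grid` lattice.
#' @param overlap_fraction target overlap coefficient in `[0, 1]`.
#' @param seed integer seed.
#' @return list of two `norm_dist` objects `d1`, `d2`.
#' @export
generate_mock_populations <- function(grid, overlap_fraction, seed = 1L) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  if (is.numeric(grid) && length(grid) == 1L) {
    grid <- expand.grid(x = seq_len(grid) - 0.5, y = seq_len(grid) - 0.5)
  }
  stopifnot(is.data.frame(grid), all(c("x", "y") %in% names(grid)),
            nrow(grid) >= 3L)
  n <- nrow(grid)
  ord <- order(grid$x, grid$y)
  third <- floor(n / 3)
  left <- ord[seq_len(third)]
  shared <- ord[seq(third + 1L, 2L * third)]
  right <- ord[seq(2L * third + 1L, n)]
  with_seed(seed, {
    w_shared <- stats::runif(length(shared))
    w_shared <- w_shared / sum(w_shared) * overlap_fraction
    p1 <- p2 <- numeric(n)
    p1[shared] <- w_shared
    p2[shared] <- w_shared
    if (overlap_fraction < 1) {
      w1 <- stats::runif(length(left))
      p1[left] <- w1 / sum(w1) * (1 - overlap_fraction)
      w2 <- stats::runif(length(right))
      p2[right] <- w2 / sum(w2) * (1 - overlap_fraction)
    }
    list(
      d1 = norm_dist(p1, grid$x, grid$y, label = "mock_1"),
      d2 = norm_dist(p2, grid$x, grid$y, label = "mock_2")
    )
  })
}
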