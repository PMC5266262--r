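# Shared fixtures, generated in code at test time.

# compact survey with a single year so month is the only control
small_bins <- function(n_cruises = 10, bins_per_cruise = 100,
                       years = 2004, months = 4:10, seed = 101) {
  cfg <- sim_config(n_cruises = n_cruises, bins_per_cruise = bins_per_cruise,
                    years = years, months = months,
                    grid_dims = c(8L, 10L), seed = seed)
  generate_survey_bins(cfg)
}

# bins with a known NB response over sst and dist_200m
nb_bins <- function(seed = 7, n_cruises = 10, bins_per_cruise = 100,
                    alpha = 0.8) {
  bins <- small_bins(n_cruises, bins_per_cruise, seed = seed)
  truth <- true_model("NB", c("(Intercept)" = -1.5, sst = 0.12,
                              dist_200m = -0.05), alpha = alpha)
  generate_counts(bins, truth, seed = seed + 1)
}

unit_lattice <- function(nc, nr) {
  g <- expand.grid(x = seq_len(nc) - 0.5, y = seq_len(nr) - 0.5)
  g$cell_id <- seq_len(nrow(g))
  g
}

# tiny reserve problem with a non-trivial optimum
toy_problem <- function(n_cells = 8, seed = 11, target = 0.3, spf = 50,
                        blm = 1, n_flips = 2000) {
  g <- unit_lattice(n_cells / 2, 2)
  surf <- with_seed_test(seed, list(
    a = abundance_surface(stats::runif(n_cells, 0, 5), x = g$x, y = g$y),
    b = abundance_surface(stats::runif(n_cells, 0, 5), x = g$x, y = g$y)
  ))
  build_problem(surf, target = target, spf = spf, blm = blm,
                n_flips = n_flips)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# exhaustive minimum of a reserve instance (<= 15 cells)
brute_force_optimum <- function(units, spec) {
  n <- units$n
  stopifnot(n <= 15)
  best <- Inf
  for (m in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    o <- reserve_objective(sel, units, spec)
    if (o < best) best <- o
  }
  best
}
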