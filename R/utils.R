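# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Draw sub-seeds (< 2^31) deterministically from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Truncated-normal draws by resampling until inside [lo, hi].
rtrunc_norm <- function(n, mean, sd, lo, hi, max_iter = 1000L) {
  stopifnot(sd > 0, lo < hi)
  x <- stats::rnorm(n, mean, sd)
  out <- x < lo | x > hi
  it <- 0L
  while (any(out) && it < max_iter) {
    x[out] <- stats::rnorm(sum(out), mean, sd)
    out <- x < lo | x > hi
    it <- it + 1L
  }
  pmin(pmax(x, lo), hi)
}

#' Percent rank of a numeric vector
#'
#' Average ranks rescaled to `[0, 100]`; ties share their average rank. Used
#' for the high- to low-use display scaling of abundance surfaces and
#' selection-frequency maps.
#'
#' @param x numeric vector (length >= 2).
#' @return numeric vector in `[0, 100]`.
#' @export
percent_rank <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  (rank(x, ties.method = "average") - 1) / (length(x) - 1) * 100
}
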