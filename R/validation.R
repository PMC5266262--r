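#' Repeated k-fold cross-validation of a count model
#'
#' Shuffles the bins and splits them into `k` folds; each fold is held
#' out, the model refit on the remaining data, and the held-out McFadden
#' pseudo-R^2 computed as `1 - ll_fit / ll_null` where both
#' log-likelihoods are evaluated on the held-out bins and the null model
#' (intercept + offset) is refit on the training split. Each repeat's
#' score is the median over folds; the decision statistic is the median
#' of the `repeats` medians. Significance is calibrated by permutation:
#' the response is permuted `n_permutations` times, each permuted dataset
#' is cross-validated (a single repeat), and the p-value is the
#' proportion of permuted statistics at least as large as the observed
#' one. Folds whose training response is degenerate (all zero) are
#' skipped with a warning and counted.
#'
#' @param model a fitted `count_fit` whose specification is refit on every
#'   split.
#' @param data survey-bin data (`nrow >= 10 * k` recommended).
#' @param k number of folds.
#' @param repeats number of shuffled repeats.
#' @param n_permutations permuted datasets for the null calibration.
#' @param seed integer seed.
#' @return object of class `kfold_validation`: `repeat_scores`,
#'   `median_of_medians`, `in_sample_pseudo_r2`, `null_scores`, `p_value`,
#'   `passed` (p < 0.05), `skipped_folds`.
#' @export
kfold_validate <- function(model, data, k = 10, repeats = 20,
                           n_permutations = 99, seed = 1L) {
  stopifnot(inherits(model, "count_fit"), is.data.frame(data), k >= 2,
            repeats >= 1, n_permutations >= 1)
  n <- nrow(data)
  if (n < 2 * k) stop("too few observations for k = ", k, call. = FALSE)
  skipped <- 0L

  cv_once <- function(d, shuffle_seed) {
    fold <- with_seed(shuffle_seed, {
      sample(rep_len(seq_len(k), n))
    })
    scores <- rep(NA_real_, k)
    for (f in seq_len(k)) {
      train <- d[fold != f, , drop = FALSE]
      test <- d[fold == f, , drop = FALSE]
      if (all(train[[model$response]] == 0) ||
          !all(unique(test$year) %in% unique(train$year))) {
        skipped <<- skipped + 1L
        next
      }
      fit_f <- tryCatch(
        suppressWarnings(
          fit_count_model(model$terms, train, family = model$family,
                          inflation_terms = model$inflation_terms,
                          response = model$response,
                          offset_var = model$offset_var,
                          controls = model$controls,
                          extra_rhs = model$extra_rhs,
                          compute_null = FALSE)
        ),
        error = function(e) NULL)
      null_f <- tryCatch(
        suppressWarnings(
          fit_count_model(list(), train, family = model$family,
                          response = model$response,
                          offset_var = model$offset_var, controls = FALSE,
                          compute_null = FALSE)
        ),
        error = function(e) NULL
      )
      if (is.null(fit_f) || is.null(null_f)) {
        skipped <<- skipped + 1L
        next
      }
      ll_fit <- sum(ll_obs(fit_f, test))
      ll_null <- sum(ll_obs(null_f, test))
      if (!is.finite(ll_fit) || !is.finite(ll_null) ||
          abs(ll_null) < 1e-12) {
        skipped <<- skipped + 1L
        next
      }
      scores[f] <- 1 - ll_fit / ll_null
    }
    if (all(is.na(scores))) {
      warning("every fold degenerate in one repeat", call. = FALSE)
    }
    stats::median(scores, na.rm = TRUE)
  }

  seeds <- derive_seeds(seed, repeats + n_permutations + 1L)
  repeat_scores <- vapply(seq_len(repeats), function(r) {
    cv_once(data, seeds[r])
  }, numeric(1))
  obs <- stats::median(repeat_scores, na.rm = TRUE)

  null_scores <- vapply(seq_len(n_permutations), function(b) {
    d <- data
    d[[model$response]] <- with_seed(seeds[repeats + b],
                                     sample(d[[model$response]]))
    cv_once(d, seeds[repeats + n_permutations + 1L])
  }, numeric(1))

  skip_warn <- skipped
  p <- mean(null_scores >= obs, na.rm = TRUE)
  structure(
    list(repeat_scores = repeat_scores,
         median_of_medians = obs,
         in_sample_pseudo_r2 = model$pseudo_r2,
         null_scores = null_scores,
         p_value = p,
         passed = is.finite(p) && p < 0.05,
         skipped_folds = skip_warn,
         k = k, repeats = repeats, n_permutations = n_permutations),
    class = "kfold_validation"
  )
}

#' @export
print.kfold_validation <- function(x, ...) {
  cat(sprintf(
    "Repeated k-fold validation (k = %d, repeats = %d, %d permutations)\n",
    x$k, x$repeats, x$n_permutations))
  cat(sprintf("held-out median-of-medians pseudo-R2 = %.4f (in-sample %.4f)\n",
              x$median_of_medians, x$in_sample_pseudo_r2))
  cat(sprintf("permutation p = %.3f -> %s", x$p_value,
              if (x$passed) "PASSED\n" else "NOT validated\n"))
  if (x$skipped_folds > 0) {
    cat("skipped folds:", x$skipped_folds, "\n")
  }
  invisible(x)
}
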