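#' Model-selection protocol configuration
#'
#' Thresholds and candidate sets of the two-stage selection protocol:
#' quadratic terms are kept at p < 0.05, linear fallbacks at p < 0.20,
#' multivariable retention requires p < 0.05, and multicollinearity is
#' bounded by VIF < 10. Year interactions are screened for depth, the
#' 200-m isobath distance, SST and UI; detection covariates are the
#' zero-inflation candidates.
#'
#' @param alpha_quadratic,alpha_linear_keep,alpha_multivariable p-value
#'   thresholds, each in (0, 1).
#' @param vif_threshold VIF bound (> 1).
#' @param interaction_candidates variables screened for year interactions.
#' @param detection_candidates zero-inflation candidate variables.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(alpha_quadratic = 0.05,
                             alpha_linear_keep = 0.20,
                             alpha_multivariable = 0.05,
                             vif_threshold = 10,
                             interaction_candidates = c("depth", "dist_200m",
                                                        "sst", "ui"),
                             detection_candidates = c("sea_state", "swell",
                                                      "visibility",
                                                      "cloud_cover",
                                                      "time_of_day")) {
  stopifnot(alpha_quadratic > 0, alpha_quadratic < 1,
            alpha_linear_keep > 0, alpha_linear_keep < 1,
            alpha_multivariable > 0, alpha_multivariable < 1,
            vif_threshold > 1)
  structure(
    list(alpha_quadratic = alpha_quadratic,
         alpha_linear_keep = alpha_linear_keep,
         alpha_multivariable = alpha_multivariable,
         vif_threshold = vif_threshold,
         interaction_candidates = interaction_candidates,
         detection_candidates = detection_candidates),
    class = "selection_config"
  )
}

# p-value of a term's highest-order coefficient in a fitted model; NA
# (e.g. rank-deficient drop) counts as 1 so such terms are never kept
term_p <- function(fit, term) {
  p <- fit$p_values[term_highest(term)]
  if (is.na(p)) 1 else as.numeric(p)
}

fit_quietly <- function(...) {
  tryCatch(fit_count_model(...), error = function(e) {
    warning("candidate fit failed: ", conditionMessage(e), call. = FALSE)
    NULL
  })
}

#' Univariate functional-form (and lag) screening
#'
#' Chooses the functional form of one candidate variable from a
#' univariate NB regression that always controls for month/year and uses
#' the area offset. Oceanographic and bathymetric variables keep a
#' quadratic when its quadratic term has p < 0.05, otherwise fall back to
#' linear when p < 0.20, otherwise drop. Distance variables take the most
#' significant of linear/quadratic/log/inverse-log; climate indices the
#' most significant (lag 0-3) x (linear/quadratic) combination; both are
#' kept only when that best p < 0.20. Ties favour simpler forms (linear,
#' then log, then inverse-log, then quadratic) and shorter lags.
#'
#' @param variable variable (column or climate-index) name.
#' @param variable_class `"oceanographic"`, `"bathymetric"`, `"distance"`
#'   or `"climate"`.
#' @param data survey-bin data.
#' @param config a [selection_config()].
#' @param response count column name.
#' @return the chosen [model_term()], or the string `"dropped"`.
#' @export
select_univariate_form <- function(variable,
                                   variable_class = c("oceanographic",
                                                      "bathymetric",
                                                      "distance", "climate"),
                                   data, config = selection_config(),
                                   response = "count") {
  variable_class <- match.arg(variable_class)

  if (variable_class %in% c("oceanographic", "bathymetric")) {
    tq <- model_term(variable, "quadratic")
    fq <- fit_quietly(list(tq), data, "nb", response = response,
                      compute_null = FALSE)
    if (!is.null(fq) && term_p(fq, tq) < config$alpha_quadratic) return(tq)
    tl <- model_term(variable, "linear")
    fl <- fit_quietly(list(tl), data, "nb", response = response,
                      compute_null = FALSE)
    if (!is.null(fl) && term_p(fl, tl) < config$alpha_linear_keep) return(tl)
    return("dropped")
  }

  candidates <- if (variable_class == "distance") {
    lapply(c("linear", "log", "invlog", "quadratic"),
           function(f) model_term(variable, f))
  } else {
    unlist(lapply(c("linear", "quadratic"), function(f) {
      lapply(0:3, function(l) model_term(variable, f, lag = l))
    }), recursive = FALSE)
  }
  ps <- vapply(candidates, function(tm) {
    f <- fit_quietly(list(tm), data, "nb", response = response,
                      compute_null = FALSE)
    if (is.null(f)) 1 else term_p(f, tm)
  }, numeric(1))
  best <- which.min(ps) # ties: first in precedence order
  if (ps[best] < config$alpha_linear_keep) candidates[[best]] else "dropped"
}

# one linear-scale column per term, used for multicollinearity screening
term_linear_design <- function(terms, data) {
  cols <- lapply(terms, function(tm) {
    v <- data[[term_column(tm)]]
    switch(tm$form,
           linear = v, quadratic = v,
           log = log(v + 1), invlog = 1 / log(v + 1))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- vapply(terms, term_column, character(1))
  X
}

#' Manual backward stepwise elimination
#'
#' Starting from all candidate terms, iteratively refits the NB model and
#' removes the term with the largest non-significant p-value (quadratic
#' pairs are judged by the quadratic term and removed as a unit) until
#' every retained term has p < 0.05. The final model must also satisfy
#' VIF < 10 across the retained terms (one linear-scale column each);
#' otherwise the highest-VIF term is removed and elimination restarts.
#' Month/year controls and the offset are never candidates for removal.
#'
#' @param candidate_terms list of [model_term()]s from the univariate
#'   stage (>= 1).
#' @param data survey-bin data.
#' @param config a [selection_config()].
#' @param response count column name.
#' @return the final `count_fit`; its `removed` attribute logs the
#'   removal order, and `controls_only` flags the all-terms-eliminated
#'   case.
#' @export
backward_stepwise <- function(candidate_terms, data,
                              config = selection_config(),
                              response = "count") {
  terms <- as_terms(candidate_terms)
  if (length(terms) == 0L) stop("need >= 1 candidate term", call. = FALSE)
  removed <- character(0)
  repeat {
    if (length(terms) == 0L) {
      fit <- fit_count_model(list(), data, "nb", response = response)
      attr(fit, "removed") <- removed
      attr(fit, "controls_only") <- TRUE
      warning("all candidate terms eliminated; returning controls-only model",
              call. = FALSE)
      return(fit)
    }
    fit <- fit_count_model(terms, data, "nb", response = response,
                           compute_null = FALSE)
    ps <- vapply(terms, function(tm) term_p(fit, tm), numeric(1))
    worst <- which.max(ps)
    if (ps[worst] >= config$alpha_multivariable) {
      removed <- c(removed, paste0(term_label(terms[[worst]]), " (p=",
                                   signif(ps[worst], 3), ")"))
      terms <- terms[-worst]
      next
    }
    if (length(terms) >= 2L) {
      v <- vif(term_linear_design(terms, data))
      if (max(v) >= config$vif_threshold) {
        bad <- which.max(v)
        removed <- c(removed, paste0(term_label(terms[[bad]]), " (VIF=",
                                     signif(max(v), 3), ")"))
        terms <- terms[-bad]
        next
      }
    }
    fit$null_log_likelihood <- null_log_likelihood(fit, data)
    fit$pseudo_r2 <- 1 - fit$log_likelihood / fit$null_log_likelihood
    attr(fit, "removed") <- removed
    attr(fit, "controls_only") <- FALSE
    return(fit)
  }
}

#' Year interactions for local/regional covariates
#'
#' Tests, for each screened variable retained in the main-effects model, a
#' likelihood-ratio test of adding its (linear-column) interaction with
#' year as a categorical variable. All individually significant
#' interactions (p < 0.05) are then included jointly. Candidates absent
#' from the main-effects model are skipped, never force-added.
#'
#' @param model main-effects NB `count_fit`.
#' @param data survey-bin data.
#' @param config a [selection_config()].
#' @return a `count_fit`, with an `interactions` attribute listing the
#'   interactions included (possibly none).
#' @export
add_year_interactions <- function(model, data, config = selection_config()) {
  stopifnot(inherits(model, "count_fit"))
  if (length(unique(data$year)) < 2L) {
    attr(model, "interactions") <- character(0)
    return(model)
  }
  present <- vapply(model$terms, function(tm) tm$variable, character(1))
  cands <- model$terms[present %in% config$interaction_candidates]
  sig <- character(0)
  for (tm in cands) {
    piece <- sprintf("%s:factor(year)", term_column(tm))
    ext <- fit_quietly(model$terms, data, model$family,
                       inflation_terms = model$inflation_terms,
                       response = model$response,
                       offset_var = model$offset_var,
                       extra_rhs = c(model$extra_rhs, piece))
    if (is.null(ext)) next
    lr <- 2 * (ext$log_likelihood - model$log_likelihood)
    df <- length(ext$coefficients) - length(model$coefficients)
    p <- stats::pchisq(max(lr, 0), df = max(df, 1L), lower.tail = FALSE)
    if (p < config$alpha_multivariable) sig <- c(sig, piece)
  }
  if (length(sig) == 0L) {
    attr(model, "interactions") <- character(0)
    return(model)
  }
  out <- fit_count_model(model$terms, data, model$family,
                         inflation_terms = model$inflation_terms,
                         response = model$response,
                         offset_var = model$offset_var,
                         extra_rhs = c(model$extra_rhs, sig))
  attr(out, "interactions") <- sig
  out
}

#' Zero-inflation choice via detection covariates and the Vuong test
#'
#' Each detection candidate is tested singly as the zero-inflation
#' covariate of a ZINB version of the model; the final model is ZINB with
#' all individually significant (p < 0.05) detection covariates when the
#' Vuong test prefers it over the NB model (one-sided p < 0.05), and the
#' NB model otherwise.
#'
#' @param model main-effects NB `count_fit`.
#' @param data survey-bin data.
#' @param config a [selection_config()].
#' @return the chosen `count_fit` (NB or ZINB), with attributes
#'   `detection_variables` and `vuong`.
#' @export
choose_inflation <- function(model, data, config = selection_config()) {
  stopifnot(inherits(model, "count_fit"), model$family == "nb")
  sig <- character(0)
  for (dv in config$detection_candidates) {
    if (is.null(data[[dv]])) next
    zf <- fit_quietly(model$terms, data, "zinb",
                      inflation_terms = list(model_term(dv, role = "inflation")),
                      response = model$response,
                      offset_var = model$offset_var,
                      extra_rhs = model$extra_rhs)
    if (is.null(zf) || !zf$converged) next
    p <- zf$inflation_p_values[dv]
    if (!is.na(p) && p < config$alpha_multivariable) sig <- c(sig, dv)
  }
  if (length(sig) == 0L) {
    attr(model, "detection_variables") <- character(0)
    return(model)
  }
  zfit <- fit_quietly(model$terms, data, "zinb",
                      inflation_terms = lapply(sig, model_term,
                                               role = "inflation"),
                      response = model$response,
                      offset_var = model$offset_var,
                      extra_rhs = model$extra_rhs)
  if (is.null(zfit) || !zfit$converged) {
    attr(model, "detection_variables") <- character(0)
    return(model)
  }
  vt <- vuong_test(model, zfit, data)
  if (vt$p_value < config$alpha_multivariable) {
    attr(zfit, "detection_variables") <- sig
    attr(zfit, "vuong") <- vt
    zfit
  } else {
    attr(model, "detection_variables") <- character(0)
    attr(model, "vuong") <- vt
    model
  }
}

#' Dominant climate index of a final model
#'
#' For each basin-scale climate index retained in the model (NPGO, PDO or
#' SOI), refits the model without it; the dominant index is the one whose
#' removal reduces the log-likelihood most. Exact ties are reported (all
#' tied names returned) rather than silently broken.
#'
#' @param model final `count_fit`.
#' @param data the data the model was fitted to.
#' @param tol tie tolerance on the log-likelihood drop.
#' @return character vector of dominant index name(s), with attribute
#'   `drops` giving each index's log-likelihood drop.
#' @export
dominant_climate_index <- function(model, data, tol = 1e-8) {
  stopifnot(inherits(model, "count_fit"))
  vars <- vapply(model$terms, function(tm) tm$variable, character(1))
  idx <- which(vars %in% c("npgo", "pdo", "soi"))
  if (length(idx) == 0L) {
    stop("model retains no basin-scale climate index", call. = FALSE)
  }
  if (length(idx) == 1L) {
    out <- vars[idx]
    attr(out, "drops") <- stats::setNames(NA_real_, vars[idx])
    return(out)
  }
  drops <- vapply(idx, function(i) {
    red <- fit_count_model(model$terms[-i], data, model$family,
                           inflation_terms = model$inflation_terms,
                           response = model$response,
                           offset_var = model$offset_var,
                           extra_rhs = model$extra_rhs)
    model$log_likelihood - red$log_likelihood
  }, numeric(1))
  names(drops) <- vars[idx]
  best <- max(drops)
  tied <- names(drops)[drops >= best - tol]
  if (length(tied) > 1L) {
    warning("dominant climate index tied: ", paste(tied, collapse = ", "),
            call. = FALSE)
  }
  out <- tied
  attr(out, "drops") <- drops
  out
}
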