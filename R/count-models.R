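#' Candidate model term
#'
#' A predictor with its functional form and (for climate indices) monthly
#' lag. Quadratic terms expand to the pair `v + I(v^2)` and are kept or
#' removed as a unit; the log and inverse-log forms are `log(v + 1)` and
#' `1/log(v + 1)` (the +1, in km for distances, avoids singularities near
#' zero).
#'
#' @param variable base variable name (a column of the data, or the index
#'   name when `lag` is given).
#' @param form one of `"linear"`, `"quadratic"`, `"log"`, `"invlog"`.
#' @param lag optional monthly lag 0-3 (climate indices only); the term
#'   then refers to the `<variable>_lag<lag>` column.
#' @param role `"count"` or `"inflation"` component.
#' @return object of class `model_term`.
#' @export
model_term <- function(variable, form = c("linear", "quadratic", "log",
                                          "invlog"),
                       lag = NULL, role = c("count", "inflation")) {
  form <- match.arg(form)
  role <- match.arg(role)
  if (!is.null(lag)) {
    stopifnot(lag %in% 0:3)
    lag <- as.integer(lag)
  }
  structure(list(variable = variable, form = form, lag = lag, role = role),
            class = "model_term")
}

term_column <- function(term) {
  if (is.null(term$lag)) term$variable
  else paste0(term$variable, "_lag", term$lag)
}

term_rhs <- function(term) {
  v <- term_column(term)
  switch(term$form,
         linear = v,
         quadratic = c(v, sprintf("I(%s^2)", v)),
         log = sprintf("log(%s + 1)", v),
         invlog = sprintf("I(1/log(%s + 1))", v))
}

# formula piece whose Wald p-value judges the whole term (the quadratic
# term for quadratic pairs, the single transformed column otherwise)
term_highest <- function(term) {
  rhs <- term_rhs(term)
  rhs[length(rhs)]
}

term_label <- function(term) {
  paste0(term_column(term), " [", term$form, "]")
}

as_terms <- function(terms) {
  if (is.null(terms)) return(list())
  if (inherits(terms, "model_term")) return(list(terms))
  lapply(terms, function(t) {
    if (inherits(t, "model_term")) t
    else if (is.character(t) && length(t) == 1L) model_term(t)
    else stop("terms must be model_term objects or variable names",
              call. = FALSE)
  })
}

control_rhs <- function(data) {
  out <- character(0)
  if (length(unique(data$month)) > 1L) out <- c(out, "month", "I(month^2)")
  if (length(unique(data$year)) > 1L) out <- c(out, "factor(year)")
  out
}

build_count_formula <- function(terms, data, response, offset_var,
                                controls = TRUE, extra_rhs = character(0)) {
  rhs <- unlist(lapply(terms, term_rhs), use.names = FALSE)
  if (controls) rhs <- c(rhs, control_rhs(data))
  rhs <- c(rhs, extra_rhs)
  if (length(rhs) == 0L) rhs <- "1"
  stats::as.formula(
    paste(response, "~", paste(rhs, collapse = " + "),
          "+ offset(log(", offset_var, "))"),
    env = globalenv()
  )
}

check_columns <- function(terms, data) {
  cols <- vapply(terms, term_column, character(1))
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop("missing covariate column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Fit a count regression for binned seabird counts
#'
#' Maximum-likelihood NB2 (variance `mu + alpha mu^2`, log link) or
#' zero-inflated NB2 regression with `ln(bin area)` as offset, controlling
#' for month (quadratic) and year (categorical) whenever the data span
#' more than one. The inflation component (ZINB only) is a logit model
#' over detection covariates. Non-convergence is flagged on the returned
#' object, never silently dropped.
#'
#' @param terms list of [model_term()]s (or bare variable names, taken as
#'   linear) for the count component.
#' @param data survey-bin data with the response, covariates, `month`,
#'   `year` and the offset column.
#' @param family `"nb"` or `"zinb"`.
#' @param inflation_terms detection covariates for the structural-zero
#'   logit (ZINB only); linear terms.
#' @param response,offset_var column names of the count and the surveyed
#'   area (km^2).
#' @param controls include the month/year controls (disable only for
#'   null models).
#' @param extra_rhs additional raw formula pieces (used internally for
#'   year interactions).
#' @param compute_null also fit the intercept-only null model for the
#'   McFadden pseudo-R^2 (skipped inside screening/cross-validation
#'   loops that only need coefficients and likelihoods).
#' @return object of class `count_fit` with components including
#'   `coefficients`, `se`, `p_values`, `alpha`, `log_likelihood`,
#'   `null_log_likelihood`, `pseudo_r2` (McFadden), `converged`.
#' @export
fit_count_model <- function(terms, data, family = c("nb", "zinb"),
                            inflation_terms = NULL,
                            response = "count", offset_var = "area_km2",
                            controls = TRUE, extra_rhs = character(0),
                            compute_null = TRUE) {
  family <- match.arg(family)
  terms <- as_terms(terms)
  inflation_terms <- as_terms(inflation_terms)
  stopifnot(is.data.frame(data), response %in% names(data),
            offset_var %in% names(data))
  if (any(data[[offset_var]] <= 0)) {
    stop("offsets (bin areas) must be positive", call. = FALSE)
  }
  check_columns(terms, data)
  check_columns(inflation_terms, data)
  y <- data[[response]]
  if (family == "zinb" && all(y == 0)) {
    stop("all-zero response: zero-inflated model is unidentifiable",
         call. = FALSE)
  }

  fml <- build_count_formula(terms, data, response, offset_var, controls,
                             extra_rhs)

  if (family == "nb") {
    warn <- character(0)
    fit <- withCallingHandlers(
      tryCatch(
        MASS::glm.nb(fml, data = data, maxit = 100),
        error = function(e) {
          # theta estimation can diverge when the data are equidispersed;
          # refit at the Poisson boundary with a large fixed theta
          warn <<- c(warn, paste("alpha at boundary:", conditionMessage(e)))
          stats::glm(fml, data = data,
                     family = MASS::negative.binomial(theta = 1e6))
        }
      ),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    cf <- summary(fit)$coefficients
    alpha <- if (is.null(fit$theta)) 1e-6 else 1 / fit$theta
    ll <- as.numeric(stats::logLik(fit))
    converged <- isTRUE(fit$converged)
    obj <- list(
      family = "nb", fit = fit,
      coefficients = cf[, 1], se = cf[, 2], p_values = cf[, 4],
      inflation_coefficients = NULL, inflation_se = NULL,
      inflation_p_values = NULL,
      alpha = alpha, log_likelihood = ll,
      converged = converged, warnings = warn
    )
  } else {
    # drop constant inflation covariates: probability collapses to the
    # intercept-only logit
    keep <- vapply(inflation_terms, function(t) {
      stats::sd(data[[term_column(t)]]) > 0
    }, logical(1))
    inflation_terms <- inflation_terms[keep]
    zi_rhs <- unlist(lapply(inflation_terms, term_rhs), use.names = FALSE)
    zfml <- if (length(zi_rhs) == 0L) ~1 else
      stats::reformulate(zi_rhs)
    environment(zfml) <- globalenv()
    fit <- suppressWarnings(
      glmmTMB::glmmTMB(fml, ziformula = zfml, family = glmmTMB::nbinom2,
                       data = data)
    )
    sm <- summary(fit)
    cfc <- sm$coefficients$cond
    cfz <- sm$coefficients$zi
    alpha <- 1 / glmmTMB::sigma(fit)
    ll <- as.numeric(stats::logLik(fit))
    converged <- isTRUE(fit$fit$convergence == 0) &&
      isTRUE(fit$sdr$pdHess) && is.finite(ll)
    obj <- list(
      family = "zinb", fit = fit,
      coefficients = cfc[, 1], se = cfc[, 2], p_values = cfc[, 4],
      inflation_coefficients = cfz[, 1], inflation_se = cfz[, 2],
      inflation_p_values = cfz[, 4],
      alpha = alpha, log_likelihood = ll,
      converged = converged, warnings = character(0)
    )
  }

  obj$terms <- terms
  obj$inflation_terms <- inflation_terms
  obj$formula <- fml
  obj$response <- response
  obj$offset_var <- offset_var
  obj$controls <- controls
  obj$extra_rhs <- extra_rhs
  obj$n_obs <- nrow(data)
  obj$xlevels <- list(year = sort(unique(data$year)))
  cols <- unique(vapply(c(terms, inflation_terms), term_column, character(1)))
  obj$training_ranges <- lapply(
    stats::setNames(cols, cols),
    function(cn) range(data[[cn]])
  )
  class(obj) <- "count_fit"

  # McFadden null: family-matched intercept-only model with the offset
  if (compute_null) {
    obj$null_log_likelihood <- null_log_likelihood(obj, data)
    obj$pseudo_r2 <- 1 - obj$log_likelihood / obj$null_log_likelihood
  } else {
    obj$null_log_likelihood <- NA_real_
    obj$pseudo_r2 <- NA_real_
  }
  obj
}

null_log_likelihood <- function(obj, data) {
  if (length(obj$terms) == 0L && !obj$controls &&
      length(obj$extra_rhs) == 0L) {
    return(obj$log_likelihood)
  }
  nf <- fit_count_model(list(), data, family = obj$family,
                        inflation_terms = list(), response = obj$response,
                        offset_var = obj$offset_var, controls = FALSE)
  nf$log_likelihood
}

#' @rdname fit_count_model
#' @export
fit_nb <- function(terms, data, ...) {
  fit_count_model(terms, data, family = "nb", ...)
}

#' @rdname fit_count_model
#' @export
fit_zinb <- function(terms, inflation_terms, data, ...) {
  fit_count_model(terms, data, family = "zinb",
                  inflation_terms = inflation_terms, ...)
}

refit <- function(object, data) {
  fit_count_model(object$terms, data, family = object$family,
                  inflation_terms = object$inflation_terms,
                  response = object$response, offset_var = object$offset_var,
                  controls = object$controls, extra_rhs = object$extra_rhs)
}

# ---- methods -----------------------------------------------------------

#' @export
print.count_fit <- function(x, ...) {
  cat(toupper(x$family), "count model:",
      deparse(x$formula[[3]]), "\n")
  if (x$family == "zinb") {
    zn <- names(x$inflation_coefficients)
    cat("Zero inflation: ~", paste(zn, collapse = " + "), "\n")
  }
  cat(sprintf("n = %d, alpha = %.4f, logLik = %.2f, pseudo-R2 = %.4f\n",
              x$n_obs, x$alpha, x$log_likelihood, x$pseudo_r2))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.count_fit <- function(object, ...) {
  ct <- data.frame(
    estimate = object$coefficients,
    se = object$se,
    p_value = object$p_values
  )
  zt <- if (object$family == "zinb") {
    data.frame(
      estimate = object$inflation_coefficients,
      se = object$inflation_se,
      p_value = object$inflation_p_values
    )
  } else NULL
  structure(list(family = object$family, count_table = ct,
                 inflation_table = zt, alpha = object$alpha,
                 log_likelihood = object$log_likelihood,
                 null_log_likelihood = object$null_log_likelihood,
                 pseudo_r2 = object$pseudo_r2, n_obs = object$n_obs,
                 converged = object$converged),
            class = "summary.count_fit")
}

#' @export
print.summary.count_fit <- function(x, ...) {
  cat(toupper(x$family), "count model\n\nCount component:\n")
  print(round(x$count_table, 5))
  if (!is.null(x$inflation_table)) {
    cat("\nZero-inflation component (logit):\n")
    print(round(x$inflation_table, 5))
  }
  cat(sprintf("\nalpha = %.4f  logLik = %.3f  null logLik = %.3f\n",
              x$alpha, x$log_likelihood, x$null_log_likelihood))
  cat(sprintf("McFadden pseudo-R2 = %.4f  n = %d%s\n", x$pseudo_r2, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.count_fit <- function(object, component = c("count", "inflation"), ...) {
  component <- match.arg(component)
  if (component == "count") object$coefficients
  else object$inflation_coefficients
}

#' @export
logLik.count_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients) +
              length(object$inflation_coefficients) + 1L,
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.count_fit <- function(object, component = c("count", "inflation"), ...) {
  component <- match.arg(component)
  if (object$family == "nb") {
    if (component == "inflation") return(NULL)
    stats::vcov(object$fit)
  } else {
    v <- stats::vcov(object$fit)
    if (component == "count") v$cond else v$zi
  }
}

#' Predict from a fitted count model
#'
#' @param object a `count_fit`.
#' @param newdata data with the model's covariates, `month`, `year` and the
#'   offset column; defaults to refusing silently missing columns.
#' @param type `"response"` (expected count, zero inflation included),
#'   `"count"` (conditional NB mean), or `"zprob"` (structural-zero
#'   probability).
#' @param ... unused.
#' @export
predict.count_fit <- function(object, newdata = NULL,
                              type = c("response", "count", "zprob"), ...) {
  type <- match.arg(type)
  if (object$family == "nb") {
    if (type == "zprob") {
      n <- if (is.null(newdata)) object$n_obs else nrow(newdata)
      return(rep(0, n))
    }
    if (is.null(newdata)) {
      return(as.numeric(stats::fitted(object$fit)))
    }
    return(as.numeric(stats::predict(object$fit, newdata = newdata,
                                     type = "response")))
  }
  gtype <- switch(type, response = "response", count = "conditional",
                  zprob = "zprob")
  as.numeric(stats::predict(object$fit, newdata = newdata, type = gtype))
}

#' @export
fitted.count_fit <- function(object, ...) {
  stats::predict(object, type = "response")
}

#' @export
residuals.count_fit <- function(object, data = NULL,
                                type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  y <- if (is.null(data)) {
    stats::model.response(stats::model.frame(object$fit))
  } else data[[object$response]]
  mu <- stats::predict(object, newdata = data, type = "count")
  pz <- stats::predict(object, newdata = data, type = "zprob")
  m <- (1 - pz) * mu
  if (type == "response") return(y - m)
  v <- (1 - pz) * (mu + object$alpha * mu^2) + pz * (1 - pz) * mu^2
  (y - m) / sqrt(v)
}

#' Simulate responses from a fitted count model
#'
#' @param object a `count_fit`.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed.
#' @param newdata optional data to simulate at (default: training fit).
#' @param ... unused.
#' @export
simulate.count_fit <- function(object, nsim = 1, seed = NULL,
                               newdata = NULL, ...) {
  runner <- function() {
    mu <- stats::predict(object, newdata = newdata, type = "count")
    pz <- stats::predict(object, newdata = newdata, type = "zprob")
    out <- as.data.frame(lapply(seq_len(nsim), function(i) {
      y <- if (object$alpha < 1e-10) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / object$alpha)
      y[stats::runif(length(mu)) < pz] <- 0L
      y
    }))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  }
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

# per-observation log-likelihood under a fitted model
ll_obs <- function(object, data = NULL) {
  y <- if (is.null(data)) {
    stats::model.response(stats::model.frame(object$fit))
  } else data[[object$response]]
  mu <- stats::predict(object, newdata = data, type = "count")
  base <- if (object$alpha < 1e-10) {
    stats::dpois(y, mu, log = TRUE)
  } else {
    stats::dnbinom(y, mu = mu, size = 1 / object$alpha, log = TRUE)
  }
  if (object$family == "nb") return(base)
  pz <- stats::predict(object, newdata = data, type = "zprob")
  log(pz * (y == 0) + (1 - pz) * exp(base))
}

# ---- diagnostics -------------------------------------------------------

#' Boundary likelihood-ratio test of over-dispersion
#'
#' Tests `alpha = 0` (Poisson) against the NB alternative; because alpha
#' lies on the boundary of its parameter space under the null, the
#' reference distribution is the 50:50 mixture of a point mass at zero and
#' chi-squared with 1 df.
#'
#' @param fit an NB `count_fit`.
#' @param data the data the model was fitted to.
#' @return list `statistic` (LR), `p_value`, `alpha`.
#' @export
lr_test_alpha <- function(fit, data) {
  stopifnot(inherits(fit, "count_fit"), fit$family == "nb")
  if (fit$alpha < 1e-7) {
    # alpha estimated at the boundary: the NB fit is the Poisson fit
    return(list(statistic = 0, p_value = 1, alpha = fit$alpha))
  }
  pois <- stats::glm(fit$formula, data = data, family = stats::poisson())
  # per-observation NB densities avoid the numerical cancellation of the
  # packaged log-likelihood at very large theta
  ll_nb <- sum(ll_obs(fit, data))
  lr <- 2 * (ll_nb - as.numeric(stats::logLik(pois)))
  p <- if (lr <= 1e-10) 1 else
    0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  list(statistic = max(lr, 0), p_value = p, alpha = fit$alpha)
}

#' Vuong test for zero inflation
#'
#' Non-nested comparison of a ZINB fit against its NB counterpart on the
#' same data, `statistic = sqrt(n) * mean(m) / sd(m)` with `m_i` the
#' per-observation log-likelihood difference (ZINB minus NB). The p-value
#' is one-sided, favouring ZINB for positive statistics.
#'
#' @param nb,zinb fitted `count_fit` objects sharing count-component terms.
#' @param data the common data.
#' @return list `statistic`, `p_value`, `n`.
#' @export
vuong_test <- function(nb, zinb, data) {
  stopifnot(inherits(nb, "count_fit"), inherits(zinb, "count_fit"),
            nb$family == "nb", zinb$family == "zinb",
            nb$n_obs == zinb$n_obs)
  m <- ll_obs(zinb, data) - ll_obs(nb, data)
  s <- stats::sd(m)
  if (!is.finite(s) || s < 1e-12) {
    stop("identical likelihood vectors: Vuong statistic undefined",
         call. = FALSE)
  }
  stat <- sqrt(length(m)) * mean(m) / s
  list(statistic = stat, p_value = stats::pnorm(stat, lower.tail = FALSE),
       n = length(m))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing design column j on the other
#' columns. Perfectly collinear columns are reported as `Inf`.
#'
#' @param design numeric matrix or data.frame of predictor columns (no
#'   intercept column).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  stopifnot(is.numeric(X), ncol(X) >= 2L)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    if (sst <= 0) return(Inf)
    r2 <- 1 - ssr / sst
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(X))
}
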