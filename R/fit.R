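# Penalized iteratively reweighted least squares for binary outcomes.
#
# Maximises  loglik(beta) - (lambda/2) * sum_{j in mask} (sd_j * beta_j)^2,
# i.e. a ridge penalty on the *standardised* coefficients of the masked
# columns, so lambda is free of the columns' measurement scales. lambda = 0
# reduces to ordinary maximum likelihood.

irls_fit <- function(x, y, link = "logit", lambda = 0,
                     penalty_idx = integer(0), maxit = 25, tol = 1e-8) {
  stopifnot(is.matrix(x), nrow(x) == length(y), all(y %in% c(0, 1)),
            lambda >= 0)
  link <- match.arg(link, c("logit", "probit", "cloglog"))
  lk <- stats::make.link(link)
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  # scale factors for the penalty (population SD of each masked column)
  pen <- numeric(p)
  if (lambda > 0 && length(penalty_idx) > 0) {
    sds <- apply(x[, penalty_idx, drop = FALSE], 2, stats::sd)
    sds[sds == 0 | is.na(sds)] <- 1
    pen[penalty_idx] <- lambda * sds^2
  }
  P <- diag(pen, nrow = p)

  beta <- rep(0, p)
  eta <- lk$linkfun((y + 0.5) / 2)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(maxit)) {
    mu <- lk$linkinv(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    me <- pmax(lk$mu.eta(eta), 1e-10)
    w <- me^2 / (mu * (1 - mu))
    z <- eta + (y - mu) / me
    A <- crossprod(x * sqrt(w))
    b <- crossprod(x, w * z)
    beta_new <- tryCatch(
      drop(solve(A + P, b)),
      error = function(e) rlang::abort(
        "design matrix is rank deficient; remove aliased columns",
        class = "oxydose_rank_error")
    )
    if (p > 1 && max(abs(beta_new[-1])) > 15) {
      rlang::abort(
        "coefficient diverging beyond 15 on the link scale; likely perfect separation",
        class = "oxydose_separation_error"
      )
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(x %*% beta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  mu <- pmin(pmax(lk$linkinv(eta), 1e-10), 1 - 1e-10)
  me <- pmax(lk$mu.eta(eta), 1e-10)
  w <- me^2 / (mu * (1 - mu))
  A <- crossprod(x * sqrt(w))          # Fisher information at the optimum
  APinv <- solve(A + P)
  edf <- sum(diag(APinv %*% A))
  vcov <- APinv %*% A %*% APinv
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  names(beta) <- colnames(x)
  dimnames(vcov) <- list(colnames(x), colnames(x))

  list(
    coefficients = beta, vcov = vcov, log_lik = ll, edf = edf,
    aic = -2 * ll + 2 * edf, n = n, converged = converged, iterations = iter,
    link = link, lambda = lambda, penalty_idx = penalty_idx,
    fitted = mu, eta = eta
  )
}

new_oxy_fit <- function(fit, x, y, meta = list()) {
  fit$x <- x
  fit$y <- y
  fit$meta <- meta
  structure(fit, class = "oxy_fit")
}

#' Fit a binary-outcome GLM by maximum likelihood
#'
#' Plain (unpenalized) maximum-likelihood fit of a binary regression by
#' Fisher scoring, with logit, probit or complementary log-log link.
#' Convergence requires the largest coefficient change to fall below `1e-8`
#' within 25 iterations; a coefficient diverging past 15 on the link scale
#' raises a separation error rather than returning a silently unstable fit.
#'
#' @param x Numeric design matrix including an intercept column.
#' @param y Binary outcome vector (0/1).
#' @param link One of `"logit"`, `"probit"`, `"cloglog"`.
#' @return An object of class `oxy_fit` with coefficients, Fisher-information
#'   covariance, log-likelihood, effective degrees of freedom and AIC.
#' @seealso [fit_penalized_glm()], [fit_outcome_model()]
#' @export
fit_glm <- function(x, y, link = "logit") {
  new_oxy_fit(irls_fit(x, y, link = link), x, y)
}

#' Fit a ridge-penalized binary GLM on selected columns
#'
#' Maximises the log-likelihood minus `(lambda/2)` times the sum of squared
#' standardised coefficients over the columns in `penalty_idx` (typically
#' interaction terms), leaving all other columns unpenalized. The effective
#' degrees of freedom are `trace(I (I + P)^-1)` with `I` the Fisher
#' information at the optimum and `P` the diagonal penalty, and the reported
#' covariance is the sandwich `(I+P)^-1 I (I+P)^-1`. The AIC uses the
#' *unpenalized* log-likelihood at the penalized optimum together with the
#' effective degrees of freedom.
#'
#' @inheritParams fit_glm
#' @param lambda Non-negative ridge penalty; `0` reproduces [fit_glm()].
#' @param penalty_idx Integer indices of the columns of `x` to penalize.
#' @return An object of class `oxy_fit`.
#' @export
fit_penalized_glm <- function(x, y, lambda, penalty_idx, link = "logit") {
  new_oxy_fit(
    irls_fit(x, y, link = link, lambda = lambda, penalty_idx = penalty_idx),
    x, y
  )
}

#' Choose the ridge penalty by AIC
#'
#' Fits the penalized model at every value of `lambda_grid` and returns the
#' fit whose AIC (unpenalized log-likelihood plus twice the effective
#' degrees of freedom) is smallest; ties go to the smallest penalty.
#'
#' @inheritParams fit_penalized_glm
#' @param lambda_grid Non-negative candidate penalties; default a geometric
#'   grid `c(0, 0.5, 1, 2, 4, 8, 16, 32, 64)`.
#' @return A list with elements `lambda` (the selected value), `fit` (the
#'   corresponding `oxy_fit`) and `path` (a tibble of `lambda`, `aic`,
#'   `edf`, `log_lik` over the grid).
#' @export
select_penalty <- function(x, y, penalty_idx,
                           lambda_grid = c(0, 0.5, 1, 2, 4, 8, 16, 32, 64),
                           link = "logit") {
  stopifnot(length(lambda_grid) >= 1, all(lambda_grid >= 0))
  lambda_grid <- sort(unique(lambda_grid))
  fits <- purrr::map(lambda_grid, function(l) {
    fit_penalized_glm(x, y, lambda = l, penalty_idx = penalty_idx, link = link)
  })
  path <- tibble::tibble(
    lambda = lambda_grid,
    aic = purrr::map_dbl(fits, "aic"),
    edf = purrr::map_dbl(fits, "edf"),
    log_lik = purrr::map_dbl(fits, "log_lik")
  )
  best <- which.min(path$aic) # first minimum = smallest lambda on ties
  list(lambda = lambda_grid[best], fit = fits[[best]], path = path)
}

#' Likelihood-ratio test between nested unpenalized fits
#'
#' @param reduced,full `oxy_fit` objects fitted by maximum likelihood
#'   (`lambda = 0`) on the same data with the same link; the reduced model's
#'   columns must be a subset of the full model's.
#' @return A one-row tibble with `statistic` (2 times the log-likelihood
#'   difference), `df` (difference in column counts) and `p.value` (upper
#'   chi-squared tail).
#' @export
lr_test <- function(reduced, full) {
  stopifnot(inherits(reduced, "oxy_fit"), inherits(full, "oxy_fit"))
  if (reduced$n != full$n || reduced$link != full$link) {
    rlang::abort("models must be fitted on the same data with the same link")
  }
  if (reduced$lambda != 0 || full$lambda != 0) {
    rlang::abort("likelihood-ratio test requires unpenalized (lambda = 0) fits")
  }
  if (!all(names(reduced$coefficients) %in% names(full$coefficients))) {
    rlang::abort("models are not nested: reduced terms not a subset of full terms")
  }
  df <- length(full$coefficients) - length(reduced$coefficients)
  stat <- max(0, 2 * (full$log_lik - reduced$log_lik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p.value = p)
}

#' Odds ratio, compatibility interval and Wald test for one model term
#'
#' For a single linear column (the dose term, the any-exposure indicator, or
#' a binary covariate) returns `exp(beta)` with a Wald compatibility
#' interval, the Wald chi-squared statistic `(beta/se)^2` on 1 degree of
#' freedom and its p-value. Spline terms have no single-coefficient odds
#' ratio; requesting one is an error (use contrasts instead).
#'
#' @param fit An `oxy_fit`.
#' @param term Name of a coefficient.
#' @param level Interval coverage, default 0.95.
#' @return A one-row tibble: `term`, `odds_ratio`, `conf.low`, `conf.high`,
#'   `wald_chi2`, `df`, `p.value`.
#' @export
term_odds_ratio <- function(fit, term, level = 0.95) {
  stopifnot(inherits(fit, "oxy_fit"), length(term) == 1)
  if (!term %in% names(fit$coefficients)) {
    rlang::abort(paste0("unknown term: ", term))
  }
  if (grepl("'", term, fixed = TRUE)) {
    rlang::abort(
      "spline terms have no single-coefficient odds ratio; evaluate contrasts over the predictor range instead"
    )
  }
  beta <- fit$coefficients[[term]]
  se <- sqrt(diag(fit$vcov))[[term]]
  z <- stats::qnorm(1 - (1 - level) / 2)
  chi2 <- (beta / se)^2
  tibble::tibble(
    term = term,
    odds_ratio = exp(beta),
    conf.low = exp(beta - z * se),
    conf.high = exp(beta + z * se),
    wald_chi2 = chi2,
    df = 1L,
    p.value = stats::pchisq(chi2, 1, lower.tail = FALSE)
  )
}

# ---- data-frame interface -------------------------------------------------

model_covariates <- c(
  "dose_kpa", "any_exposure", "respiratory_dx", "sex", "prior_dependency",
  "patient_type", "continuous_mv", "age_years", "weight_kg", "apache_ii"
)

build_design <- function(data, n_knots = 4, interactions = FALSE,
                         knots = NULL) {
  miss <- setdiff(c(model_covariates, "icu_death"), names(data))
  if (length(miss) > 0) {
    rlang::abort(paste0("cohort data is missing required column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (anyNA(data[model_covariates])) {
    rlang::abort("cohort data contains missing covariate values; apply_exclusions() enforces complete cases")
  }
  n <- nrow(data)
  if (is.null(knots)) {
    knots <- list(
      age_years = rcs_knots(data$age_years, n_knots),
      weight_kg = rcs_knots(data$weight_kg, n_knots),
      apache_ii = rcs_knots(data$apache_ii, n_knots)
    )
  }
  any_exp <- as.numeric(data$any_exposure)
  resp <- as.numeric(data$respiratory_dx)
  cmv <- as.numeric(data$continuous_mv)
  x <- cbind(
    "(Intercept)" = rep(1, n),
    dose_kpa = data$dose_kpa,
    any_exposure = any_exp,
    respiratory_dx = resp,
    sex_male = as.numeric(data$sex == "M"),
    prior_dependency = as.numeric(data$prior_dependency),
    patient_type_medical = as.numeric(data$patient_type == "medical"),
    continuous_mv = cmv,
    rcs_basis(data$age_years, knots$age_years, prefix = "age_years"),
    rcs_basis(data$weight_kg, knots$weight_kg, prefix = "weight_kg"),
    rcs_basis(data$apache_ii, knots$apache_ii, prefix = "apache_ii")
  )
  interaction_cols <- character(0)
  if (interactions) {
    xi <- cbind(
      "any_exposure:respiratory_dx" = any_exp * resp,
      "dose_kpa:respiratory_dx" = data$dose_kpa * resp,
      "any_exposure:continuous_mv" = any_exp * cmv,
      "dose_kpa:continuous_mv" = data$dose_kpa * cmv
    )
    interaction_cols <- colnames(xi)
    x <- cbind(x, xi)
  }
  # drop constant (zero-variance) columns: e.g. every episode exposed makes
  # the spike-at-zero indicator unidentifiable alongside the intercept
  const <- apply(x[, -1, drop = FALSE], 2, function(v) diff(range(v)) == 0)
  dropped <- colnames(x)[-1][const]
  if (length(dropped) > 0) {
    rlang::warn(paste0("dropping constant column(s): ",
                       paste(dropped, collapse = ", ")))
    x <- x[, !colnames(x) %in% dropped, drop = FALSE]
    interaction_cols <- setdiff(interaction_cols, dropped)
  }
  exposure_cols <- intersect(
    c("dose_kpa", "any_exposure", interaction_cols), colnames(x)
  )
  list(x = x, y = as.numeric(data$icu_death), knots = knots,
       penalty_idx = match(interaction_cols, colnames(x)),
       exposure_cols = exposure_cols, dropped = dropped,
       interactions = interactions)
}

#' Fit the hyperoxemia mortality model on a window cohort
#'
#' Fits ICU mortality against the window's hyperoxemia dose (linear, in
#' kPa), an any-exposure indicator handling the spike at zero, respiratory
#' diagnosis, sex, prior dependency, medical/surgical admission, continuous
#' mechanical ventilation over the window, and restricted-cubic-spline terms
#' for age, weight and APACHE II. Optional exposure-by-respiratory-diagnosis
#' and exposure-by-ventilation interactions (both the indicator and the dose
#' component of exposure) can be added and ridge-penalized, with the penalty
#' chosen by AIC when `lambda_grid` is supplied.
#'
#' @param data A window cohort: one row per episode with columns
#'   `icu_death`, `dose_kpa`, `any_exposure`, `respiratory_dx`, `sex`,
#'   `prior_dependency`, `patient_type`, `continuous_mv`, `age_years`,
#'   `weight_kg`, `apache_ii` (as produced by [build_nested_cohorts()]).
#' @param link Link function: `"logit"` (default), `"probit"` or
#'   `"cloglog"`.
#' @param interactions Add exposure interaction terms? Default `FALSE`.
#' @param lambda Fixed ridge penalty on the interaction columns (ignored
#'   when `lambda_grid` is given). Default 0.
#' @param lambda_grid Optional penalty grid for AIC selection; see
#'   [select_penalty()].
#' @param n_knots Knots per restricted cubic spline, default 4.
#' @return An `oxy_fit`; see [tidy.oxy_fit()], [glance.oxy_fit()],
#'   [term_odds_ratio()], [bootstrap_validate()],
#'   [average_treatment_effect()].
#' @export
fit_outcome_model <- function(data, link = "logit", interactions = FALSE,
                              lambda = 0, lambda_grid = NULL, n_knots = 4) {
  d <- build_design(data, n_knots = n_knots, interactions = interactions)
  meta <- list(
    knots = d$knots, interactions = interactions, dropped = d$dropped,
    exposure_cols = d$exposure_cols, n_knots = n_knots,
    episode_id = if ("episode_id" %in% names(data)) data$episode_id else seq_len(nrow(data)),
    window_h = if ("window_h" %in% names(data)) unique(data$window_h)[1] else NA_real_
  )
  if (!is.null(lambda_grid) && length(d$penalty_idx) > 0) {
    sel <- select_penalty(d$x, d$y, d$penalty_idx, lambda_grid, link = link)
    fit <- sel$fit
    meta$lambda_path <- sel$path
  } else {
    fit <- irls_fit(d$x, d$y, link = link, lambda = lambda,
                    penalty_idx = d$penalty_idx)
    fit <- new_oxy_fit(fit, d$x, d$y)
  }
  fit$meta <- meta
  fit$penalty_idx <- d$penalty_idx
  fit
}

#' Predict mortality risk from a fitted hyperoxemia model
#'
#' @param object An `oxy_fit` from [fit_outcome_model()].
#' @param newdata Optional cohort data frame; spline knots from the original
#'   fit are reused. Defaults to the training design.
#' @param type `"response"` (probability) or `"link"` (linear predictor).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.oxy_fit <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    x <- object$x
  } else {
    d <- build_design(newdata, n_knots = object$meta$n_knots %||% 4,
                      interactions = isTRUE(object$meta$interactions),
                      knots = object$meta$knots)
    x <- d$x[, names(object$coefficients), drop = FALSE]
  }
  eta <- unname(drop(x %*% object$coefficients))
  if (type == "link") return(eta)
  stats::make.link(object$link)$linkinv(eta)
}

#' @export
print.oxy_fit <- function(x, ...) {
  cat("<oxy_fit> ", x$link, " model, n = ", x$n,
      ", terms = ", length(x$coefficients),
      if (x$lambda > 0) paste0(", lambda = ", signif(x$lambda, 3)) else "",
      "\n  log-likelihood = ", signif(x$log_lik, 6),
      ", edf = ", signif(x$edf, 4),
      ", AIC = ", signif(x$aic, 6),
      if (!x$converged) "\n  WARNING: did not converge" else "",
      "\n", sep = "")
  invisible(x)
}

#' Tidy coefficient table for a fitted hyperoxemia model
#'
#' @param x An `oxy_fit`.
#' @param exponentiate Report odds-ratio scale (`exp(estimate)`)?
#' @param conf.level Interval coverage, default 0.95.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`
#'   (Wald z), `p.value`, `conf.low`, `conf.high`.
#' @method tidy oxy_fit
#' @export
tidy.oxy_fit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  q <- stats::qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(unname(z))),
    conf.low = unname(x$coefficients - q * se),
    conf.high = unname(x$coefficients + q * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' One-row model summary
#'
#' @param x An `oxy_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_terms`, `log_lik`, `edf`, `aic`, `lambda`,
#'   `link`, `converged`.
#' @method glance oxy_fit
#' @export
glance.oxy_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_terms = length(x$coefficients), log_lik = x$log_lik,
    edf = x$edf, aic = x$aic, lambda = x$lambda, link = x$link,
    converged = x$converged
  )
}
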