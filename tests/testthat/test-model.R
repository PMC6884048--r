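test_that("an intercept-only fit on a balanced outcome returns p = 0.5", {
  x <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rep(c(0, 1), 50)
  fit <- fit_glm(x, y)
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-10)
  expect_equal(unname(fit$fitted[1]), 0.5, tolerance = 1e-10)
  expect_equal(fit$edf, 1)
})

test_that("maximum-likelihood fits agree with stats::glm across links", {
  set.seed(601)
  for (i in 1:20) {
    d <- sim_logit_data(200, c(-1, 0.8, -0.5, 0.3))
    link <- sample(c("logit", "probit", "cloglog"), 1)
    fit <- fit_glm(d$x, d$y, link = link)
    ref <- suppressWarnings(
      stats::glm.fit(d$x, d$y, family = stats::binomial(link = link),
                     control = stats::glm.control(epsilon = 1e-12,
                                                  maxit = 100))
    )
    expect_lt(max(abs(coef(fit) - ref$coefficients)), 1e-6)
    expect_equal(fit$log_lik,
                 sum(stats::dbinom(d$y, 1, ref$fitted.values, log = TRUE)),
                 tolerance = 1e-8)
  }
})

test_that("the logit fit agrees with a direct likelihood optimizer", {
  set.seed(602)
  d <- sim_logit_data(500, c(-0.5, 1, -1))
  nll <- function(b) -sum(d$y * (d$x %*% b) - log1p(exp(d$x %*% b)))
  grad <- function(b) drop(crossprod(d$x, stats::plogis(d$x %*% b) - d$y))
  opt <- stats::optim(rep(0, 3), nll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  expect_lt(max(abs(coef(fit_glm(d$x, d$y)) - opt$par)), 1e-6)
})

test_that("a known effect is recovered inside its Wald interval at large n", {
  set.seed(603)
  n <- 50000
  x <- cbind("(Intercept)" = 1, x1 = stats::rbinom(n, 1, 0.5))
  y <- as.numeric(stats::runif(n) < stats::plogis(-2 + log(1.5) * x[, 2]))
  td <- tidy(fit_glm(x, y))
  expect_gt(log(1.5), td$conf.low[2])
  expect_lt(log(1.5), td$conf.high[2])
})

test_that("perfect separation raises a dedicated error", {
  x <- cbind("(Intercept)" = 1, x1 = c(rep(0, 20), rep(1, 20)))
  y <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_glm(x, y), class = "oxydose_separation_error")
})

test_that("zero penalty reproduces the MLE and infinite penalty kills masked terms", {
  set.seed(604)
  d <- sim_logit_data(2000, c(-1.5, 0.6, -0.4, 0.2, 0.1))
  mask <- 4:5
  f0 <- fit_penalized_glm(d$x, d$y, lambda = 0, penalty_idx = mask)
  fml <- fit_glm(d$x, d$y)
  expect_lt(max(abs(coef(f0) - coef(fml))), 1e-6)
  expect_equal(f0$edf, ncol(d$x))
  fInf <- fit_penalized_glm(d$x, d$y, lambda = 1e9, penalty_idx = mask)
  expect_lt(max(abs(coef(fInf)[mask])), 1e-4)
  expect_lt(abs(fInf$edf - (ncol(d$x) - length(mask))), 0.01)
})

test_that("effective df matches an eigen-decomposition of the trace formula", {
  set.seed(605)
  d <- sim_logit_data(1500, c(-1, 0.5, -0.3, 0.4, -0.2))
  mask <- 3:5
  lambda <- 4
  fit <- fit_penalized_glm(d$x, d$y, lambda = lambda, penalty_idx = mask)
  lk <- stats::make.link("logit")
  eta <- drop(d$x %*% coef(fit))
  w <- lk$mu.eta(eta)^2 / (lk$linkinv(eta) * (1 - lk$linkinv(eta)))
  A <- crossprod(d$x * sqrt(w))
  pen <- numeric(ncol(d$x))
  pen[mask] <- lambda * apply(d$x[, mask, drop = FALSE], 2, stats::sd)^2
  ev <- eigen(solve(A + diag(pen)) %*% A, only.values = TRUE)$values
  expect_equal(fit$edf, sum(Re(ev)), tolerance = 1e-8)
})

test_that("penalty selection minimises AIC and honours its identities", {
  set.seed(606)
  d <- sim_logit_data(3000, c(-1.2, 0.5, -0.4, 0, 0))
  mask <- 4:5
  one <- select_penalty(d$x, d$y, mask, lambda_grid = 2)
  expect_equal(one$lambda, 2)
  sel <- select_penalty(d$x, d$y, mask)
  expect_equal(sel$fit$aic, min(sel$path$aic))
  # reported AIC is exactly -2 log L + 2 edf
  expect_identical(sel$fit$aic, -2 * sel$fit$log_lik + 2 * sel$fit$edf)
  # the unpenalized log-likelihood is the maximum over the grid
  expect_true(all(sel$path$log_lik <= sel$path$log_lik[1] + 1e-10))
})

test_that("AIC-driven shrinkage favours a positive penalty under a null signal", {
  set.seed(607)
  hits <- 0
  for (r in 1:30) {
    d <- sim_logit_data(3000, c(-1.5, 0.6, -0.4, 0, 0, 0, 0))
    sel <- select_penalty(d$x, d$y, 4:7,
                          lambda_grid = c(0, 1, 4, 16, 64))
    hits <- hits + (sel$lambda > 0)
  }
  expect_gte(hits, 18) # shrinkage is AIC-favoured when the truth is null
})

test_that("the likelihood-ratio test matches its defining arithmetic", {
  set.seed(608)
  d <- sim_logit_data(1000, c(-1, 0.7, 0.3))
  full <- fit_glm(d$x, d$y)
  reduced <- fit_glm(d$x[, 1:2], d$y)
  lr <- lr_test(reduced, full)
  expect_equal(lr$statistic, 2 * (full$log_lik - reduced$log_lik))
  expect_equal(lr$df, 1)
  expect_equal(lr$p.value,
               stats::pchisq(lr$statistic, 1, lower.tail = FALSE))
  # identical models: zero statistic, p = 1
  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # non-nested models refuse
  other <- fit_glm(d$x[, c(1, 3)], d$y)
  expect_error(lr_test(other, reduced), "not nested")
  pen <- fit_penalized_glm(d$x, d$y, lambda = 2, penalty_idx = 3)
  expect_error(lr_test(reduced, pen), "unpenalized")
})

test_that("nested unpenalized fits never lose log-likelihood when a column is added", {
  set.seed(609)
  for (r in 1:5) {
    d <- sim_logit_data(800, c(-1, 0.5, 0))
    red <- fit_glm(d$x[, 1:2], d$y)
    full <- fit_glm(d$x, d$y)
    expect_gte(full$log_lik, red$log_lik - 1e-10)
  }
})

test_that("published odds-ratio arithmetic reproduces from printed inputs", {
  # chi-square 5.815 on 1 df corresponds to p = 0.016 at 3 decimals
  beta <- log(1.74)
  se <- beta / sqrt(5.815)
  fake <- structure(
    list(coefficients = c(any_exposure = beta),
         vcov = matrix(se^2, 1, 1, dimnames = list("any_exposure",
                                                   "any_exposure")),
         link = "logit", lambda = 0, n = 1),
    class = "oxy_fit"
  )
  or <- term_odds_ratio(fake, "any_exposure")
  expect_equal(round(or$conf.low, 2), 1.11)
  expect_equal(or$wald_chi2, 5.815, tolerance = 1e-10)
  expect_equal(round(or$p.value, 3), 0.016)
  expect_equal(or$odds_ratio, 1.74)
})

test_that("odds-ratio helper handles identities and refuses spline terms", {
  fake <- structure(
    list(coefficients = c(dose_kpa = 0, "age_years'" = 1),
         vcov = diag(c(0.04, 0.01)) |>
           (\(m) {dimnames(m) <- list(c("dose_kpa", "age_years'"),
                                      c("dose_kpa", "age_years'")); m})(),
         link = "logit", lambda = 0, n = 1),
    class = "oxy_fit"
  )
  or <- term_odds_ratio(fake, "dose_kpa")
  expect_equal(or$odds_ratio, 1)
  expect_true(or$conf.low < 1 && or$conf.high > 1)
  expect_error(term_odds_ratio(fake, "age_years'"), "spline")
  expect_error(term_odds_ratio(fake, "nope"), "unknown term")
  fake$coefficients["dose_kpa"] <- 0.405465
  expect_equal(round(term_odds_ratio(fake, "dose_kpa")$odds_ratio, 4), 1.5)
})

test_that("the cohort-level model fits, predicts, and drops a constant indicator", {
  nested <- test_cohort(n = 4000, seed = 112)
  fit <- fit_outcome_model(nested)
  expect_s3_class(fit, "oxy_fit")
  expect_true(fit$converged)
  expect_true(all(c("dose_kpa", "any_exposure", "apache_ii''") %in%
                    names(coef(fit))))
  # predictions round-trip through newdata
  expect_equal(predict(fit, newdata = nested), unname(fit$fitted),
               tolerance = 1e-12)
  g <- glance(fit)
  expect_identical(g$aic, -2 * g$log_lik + 2 * g$edf)
  # spike-at-zero guard: everyone exposed drops the indicator with a warning
  all_exposed <- dplyr::filter(nested, any_exposure)
  expect_warning(fit2 <- fit_outcome_model(all_exposed),
                 "constant column")
  expect_false("any_exposure" %in% names(coef(fit2)))
  expect_true("dose_kpa" %in% names(coef(fit2)))
})

test_that("interaction terms enter the penalized mask and shrink as one block", {
  nested <- test_cohort(n = 5000, seed = 113)
  fit <- fit_outcome_model(nested, interactions = TRUE, lambda = 1e9)
  inter <- grep(":", names(coef(fit)), value = TRUE)
  expect_length(inter, 4)
  expect_lt(max(abs(coef(fit)[inter])), 1e-4)
  # main exposure terms are never penalized
  base <- fit_outcome_model(nested)
  expect_equal(coef(fit)[["dose_kpa"]], coef(base)[["dose_kpa"]],
               tolerance = 0.05)
})

test_that("alternative links agree on the direction of the exposure effect", {
  cfg_true <- modifyList(cohort_config()$true_coefficients,
                         list(any_exposure = log(2)))
  nested <- test_cohort(n = 8000, seed = 114, true_coefficients = cfg_true)
  for (link in c("logit", "probit", "cloglog")) {
    fit <- fit_outcome_model(nested, link = link)
    expect_gt(coef(fit)[["any_exposure"]], 0)
  }
})
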