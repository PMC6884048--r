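#' Concordance index (AUROC) of predicted risks
#'
#' Probability that a randomly chosen event case receives a higher predicted
#' risk than a randomly chosen non-case, with ties counting one half;
#' identical to the area under the receiver-operating-characteristic curve.
#' Computed from midranks, which matches exhaustive pair enumeration
#' exactly.
#'
#' @param predicted Numeric predicted risks (any monotone score works; the
#'   c-index is rank-based).
#' @param outcome Binary outcomes (0/1 or logical); both classes must be
#'   present.
#' @return A single value in `[0, 1]`.
#' @export
c_index <- function(predicted, outcome) {
  y <- as.numeric(outcome)
  stopifnot(length(predicted) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("c-index undefined: outcome has a single class",
                 class = "oxydose_metric_error")
  }
  r <- rank(predicted)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and observed binary
#' outcome; lower is better, and a constant prediction of 0.5 scores 0.25.
#'
#' @param predicted Predicted probabilities in `[0, 1]`.
#' @param outcome Binary outcomes (0/1 or logical).
#' @return A single value in `[0, 1]`.
#' @export
brier_score <- function(predicted, outcome) {
  y <- as.numeric(outcome)
  stopifnot(length(predicted) == length(y), all(y %in% c(0, 1)),
            all(predicted >= 0 & predicted <= 1))
  mean((predicted - y)^2)
}

#' Precision-recall curve and average precision
#'
#' Precision and recall at every distinct prediction threshold (thresholds
#' descending, so recall is non-decreasing down the rows), plus average
#' precision by step-wise integration
#' \eqn{\sum_k (R_k - R_{k-1}) P_k}. With constant predictions the curve
#' collapses to a single point and the average precision equals the outcome
#' prevalence.
#'
#' @inheritParams c_index
#' @return A tibble with columns `threshold`, `precision`, `recall`, with
#'   the average precision attached as attribute `"average_precision"` (see
#'   [average_precision()]).
#' @export
precision_recall <- function(predicted, outcome) {
  y <- as.numeric(outcome)
  stopifnot(length(predicted) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  if (n1 == 0 || sum(y == 0) == 0) {
    rlang::abort("precision-recall undefined: outcome has a single class",
                 class = "oxydose_metric_error")
  }
  o <- order(predicted, decreasing = TRUE)
  p_sorted <- predicted[o]
  y_sorted <- y[o]
  tp <- cumsum(y_sorted)
  np <- seq_along(y_sorted)
  # evaluate only at the last index of each tied block of thresholds
  last <- !duplicated(p_sorted, fromLast = TRUE)
  curve <- tibble::tibble(
    threshold = p_sorted[last],
    precision = tp[last] / np[last],
    recall = tp[last] / n1
  )
  ap <- sum(diff(c(0, curve$recall)) * curve$precision)
  attr(curve, "average_precision") <- ap
  curve
}

#' Average precision of predicted risks
#'
#' @inheritParams c_index
#' @return The step-integrated area under the precision-recall curve.
#' @export
average_precision <- function(predicted, outcome) {
  attr(precision_recall(predicted, outcome), "average_precision")
}

# Logistic recalibration: slope of outcome on the linear predictor, and
# intercept with the linear predictor as offset (calibration-in-the-large).
calibration_coefficients <- function(eta, y, link = "logit") {
  fam <- stats::binomial(link = link)
  slope <- tryCatch(
    unname(stats::coef(stats::glm(y ~ eta, family = fam))[2]),
    error = function(e) NA_real_, warning = function(w) {
      suppressWarnings(unname(stats::coef(stats::glm(y ~ eta, family = fam))[2]))
    }
  )
  intercept <- tryCatch(
    unname(stats::coef(suppressWarnings(
      stats::glm(y ~ 1 + offset(eta), family = fam)))[1]),
    error = function(e) NA_real_
  )
  c(calibration_slope = slope, calibration_intercept = intercept)
}

validation_metrics <- function(p, eta, y, link) {
  c(
    c_index = c_index(p, y),
    brier = brier_score(p, y),
    calibration_coefficients(eta, y, link)
  )
}

#' Bootstrap optimism-corrected model validation
#'
#' Standard optimism bootstrap: the model is refitted on each of `B`
#' resamples (same penalty, link and design columns; spline knots are held
#' at their original locations), evaluated both on the resample it was
#' fitted to and on the original data, and the mean train-minus-test gap —
#' the optimism — is subtracted from the apparent c-index, Brier score and
#' calibration slope/intercept. Average precision and AIC are reported as
#' apparent values, as is conventional. Resamples in which the refit fails
#' (separation or non-convergence) are skipped and counted.
#'
#' @param fit An `oxy_fit` from [fit_outcome_model()] (or the matrix-level
#'   fitters).
#' @param B Number of bootstrap resamples, default 500.
#' @param seed Integer seed making the report reproducible.
#' @param smooth_points Number of points for the calibration smooth curve.
#' @return An object of class `oxy_validation`: `metrics` (tibble with
#'   `metric`, `apparent`, `optimism`, `corrected`), `calibration` (decile
#'   bins: mean predicted vs observed rate), `smooth` (lowess calibration
#'   curve, apparent and recalibrated/corrected), `B`, `B_used`, `skipped`,
#'   `seed`.
#' @export
bootstrap_validate <- function(fit, B = 500, seed = 1L, smooth_points = 80) {
  stopifnot(inherits(fit, "oxy_fit"), B >= 1)
  withr::local_seed(seed)
  x <- fit$x
  y <- fit$y
  n <- length(y)
  lk <- stats::make.link(fit$link)
  eta_app <- drop(x %*% fit$coefficients)
  p_app <- lk$linkinv(eta_app)
  apparent <- validation_metrics(p_app, eta_app, y, fit$link)

  opt <- matrix(NA_real_, nrow = B, ncol = length(apparent),
                dimnames = list(NULL, names(apparent)))
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(
      irls_fit(x[idx, , drop = FALSE], y[idx], link = fit$link,
               lambda = fit$lambda, penalty_idx = fit$penalty_idx),
      error = function(e) NULL
    )
    if (is.null(fb) || !fb$converged) {
      skipped <- skipped + 1L
      next
    }
    eta_tr <- drop(x[idx, , drop = FALSE] %*% fb$coefficients)
    eta_te <- drop(x %*% fb$coefficients)
    m_tr <- validation_metrics(lk$linkinv(eta_tr), eta_tr, y[idx], fit$link)
    m_te <- validation_metrics(lk$linkinv(eta_te), eta_te, y, fit$link)
    opt[b, ] <- m_tr - m_te
  }
  optimism <- colMeans(opt, na.rm = TRUE)
  # Brier optimism is train-minus-test and negative for an overfitted model
  # (training error underestimates); subtracting it raises the corrected
  # Brier, as it should.
  corrected <- apparent - optimism

  metrics <- tibble::tibble(
    metric = c(names(apparent), "average_precision", "aic"),
    apparent = c(unname(apparent), average_precision(p_app, y), fit$aic),
    optimism = c(unname(optimism), NA_real_, NA_real_),
    corrected = c(unname(corrected), NA_real_, NA_real_)
  )

  bins <- tibble::tibble(p = p_app, y = y) |>
    dplyr::mutate(bin = dplyr::ntile(.data$p, 10)) |>
    dplyr::summarise(
      pred_mean = mean(.data$p), obs_rate = mean(.data$y),
      n = dplyr::n(), .by = "bin"
    ) |>
    dplyr::arrange(.data$bin)

  lo <- stats::lowess(p_app, y, iter = 0)
  grid <- seq(min(p_app), max(p_app), length.out = smooth_points)
  smooth_app <- stats::approx(lo$x, lo$y, xout = grid, ties = mean)$y
  a_c <- corrected[["calibration_intercept"]]
  b_c <- corrected[["calibration_slope"]]
  smooth_corr <- lk$linkinv(a_c + b_c * lk$linkfun(pmin(pmax(grid, 1e-10),
                                                        1 - 1e-10)))
  structure(
    list(
      metrics = metrics,
      calibration = bins,
      smooth = tibble::tibble(predicted = grid, apparent = smooth_app,
                              corrected = smooth_corr),
      B = B, B_used = B - skipped, skipped = skipped, seed = seed
    ),
    class = "oxy_validation"
  )
}

#' @export
print.oxy_validation <- function(x, ...) {
  cat("<oxy_validation> optimism bootstrap, B =", x$B,
      if (x$skipped > 0) paste0("(", x$skipped, " skipped)"), "\n")
  print(x$metrics)
  invisible(x)
}

#' Tidy the metrics of a bootstrap validation report
#'
#' @param x An `oxy_validation`.
#' @param ... Unused.
#' @return The metrics tibble (`metric`, `apparent`, `optimism`,
#'   `corrected`).
#' @method tidy oxy_validation
#' @export
tidy.oxy_validation <- function(x, ...) x$metrics

#' One-row summary of a bootstrap validation report
#'
#' @param x An `oxy_validation`.
#' @param ... Unused.
#' @return A tibble with corrected c-index, Brier score, calibration slope
#'   and intercept plus bookkeeping columns.
#' @method glance oxy_validation
#' @export
glance.oxy_validation <- function(x, ...) {
  m <- x$metrics
  val <- function(k) m$corrected[m$metric == k]
  tibble::tibble(
    c_index = val("c_index"),
    brier = val("brier"),
    calibration_slope = val("calibration_slope"),
    calibration_intercept = val("calibration_intercept"),
    B = x$B, B_used = x$B_used, seed = x$seed
  )
}
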