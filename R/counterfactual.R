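#' Average treatment effect of hyperoxemia exposure by g-computation
#'
#' Contrasts each episode's fitted mortality risk with the counterfactual
#' risk had its hyperoxemia exposure been zero: the dose, the any-exposure
#' indicator and every interaction column involving them are set to 0, and
#' risks are recomputed from the same fitted model (plug-in g-computation).
#' Episodes that were never exposed have identical factual and
#' counterfactual design rows, so their risk pair lies on the identity line
#' bit-exactly. The average treatment effect is the mean risk difference,
#' reported in percentage points of ICU mortality.
#'
#' @param fit An `oxy_fit` from [fit_outcome_model()].
#' @return An object of class `oxy_ate`: `pairs` (tibble with `episode_id`,
#'   `risk_observed`, `risk_zero`), `ate_pp` (mean difference in percentage
#'   points), `n_on_identity` (episodes with zero observed exposure),
#'   `window_h`.
#' @export
average_treatment_effect <- function(fit) {
  stopifnot(inherits(fit, "oxy_fit"))
  cols <- fit$meta$exposure_cols
  if (is.null(cols)) {
    cols <- intersect(c("dose_kpa", "any_exposure"), names(fit$coefficients))
  }
  x <- fit$x
  cols <- intersect(cols, colnames(x))
  xcf <- x
  # with no exposure columns left (e.g. nobody exposed, so the indicator
  # was dropped as constant) the counterfactual equals the factual world
  if (length(cols) > 0) xcf[, cols] <- 0
  lk <- stats::make.link(fit$link)
  risk_obs <- lk$linkinv(drop(x %*% fit$coefficients))
  risk_zero <- lk$linkinv(drop(xcf %*% fit$coefficients))
  unexposed <- if (length(cols) == 0) rep(TRUE, nrow(x)) else
    rowSums(abs(x[, cols, drop = FALSE])) == 0
  ids <- fit$meta$episode_id
  if (is.null(ids) || length(ids) != length(risk_obs)) {
    ids <- seq_along(risk_obs)
  }
  structure(
    list(
      pairs = tibble::tibble(
        episode_id = ids,
        risk_observed = risk_obs,
        risk_zero = risk_zero
      ),
      ate_pp = mean(risk_obs - risk_zero) * 100,
      n_on_identity = sum(unexposed),
      window_h = fit$meta$window_h %||% NA_real_
    ),
    class = "oxy_ate"
  )
}

#' @export
print.oxy_ate <- function(x, ...) {
  cat("<oxy_ate> window ", x$window_h, " h: ATE = ",
      signif(x$ate_pp, 3), " percentage points (",
      x$n_on_identity, " of ", nrow(x$pairs),
      " episodes unexposed, on the identity line)\n", sep = "")
  invisible(x)
}

#' Tidy an average-treatment-effect report
#'
#' @param x An `oxy_ate`.
#' @param ... Unused.
#' @return A one-row tibble: `window_h`, `ate_pp`, `n`, `n_on_identity`,
#'   `mean_risk_observed`, `mean_risk_zero`.
#' @method tidy oxy_ate
#' @export
tidy.oxy_ate <- function(x, ...) {
  tibble::tibble(
    window_h = x$window_h,
    ate_pp = x$ate_pp,
    n = nrow(x$pairs),
    n_on_identity = x$n_on_identity,
    mean_risk_observed = mean(x$pairs$risk_observed),
    mean_risk_zero = mean(x$pairs$risk_zero)
  )
}
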