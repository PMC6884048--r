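#' Quantile-based knot placement for restricted cubic splines
#'
#' Places `n_knots` knots at the conventional quantiles used in regression
#' modelling practice: `(0.10, 0.50, 0.90)` for 3 knots,
#' `(0.05, 0.35, 0.65, 0.95)` for 4, `(0.05, 0.275, 0.50, 0.725, 0.95)` for
#' 5, and outer quantiles 0.05/0.95 with equal spacing for 6 or 7. For other
#' counts, knots are spread evenly between the 0.05 and 0.95 quantiles.
#'
#' @param x Numeric predictor values (NAs dropped).
#' @param n_knots Number of knots, at least 3. Default 4.
#' @return Strictly increasing numeric vector of knot locations.
#' @export
#' @examples
#' rcs_knots(0:100, 4) # approximately 5, 35, 65, 95
rcs_knots <- function(x, n_knots = 4) {
  stopifnot(is.numeric(x), length(n_knots) == 1, n_knots >= 3)
  x <- x[!is.na(x)]
  if (length(unique(x)) < n_knots) {
    rlang::abort("too few distinct values to place the requested knots")
  }
  probs <- switch(as.character(n_knots),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
    "7" = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975),
    seq(0.05, 0.95, length.out = n_knots)
  )
  knots <- unname(stats::quantile(x, probs, type = 7))
  if (any(diff(knots) <= 0)) {
    rlang::abort("quantile knots are not strictly increasing; predictor too discrete for this many knots")
  }
  knots
}

#' Restricted cubic spline basis (truncated power form)
#'
#' Builds the k-1 design columns of a restricted (natural) cubic spline with
#' knots `knots`: the identity column plus k-2 nonlinear columns that are
#' cubic between the boundary knots and exactly linear outside them. The
#' nonlinear columns use the truncated-power construction normalised by the
#' squared knot span, `(t_k - t_1)^2`, so all columns live on comparable
#' scales — this keeps penalised fitting well conditioned.
#'
#' For knots \eqn{t_1 < \dots < t_k} the j-th nonlinear column is
#' \deqn{\big[(x - t_j)_+^3 - (x - t_{k-1})_+^3 \tfrac{t_k - t_j}{t_k - t_{k-1}}
#'   + (x - t_k)_+^3 \tfrac{t_{k-1} - t_j}{t_k - t_{k-1}}\big] / (t_k - t_1)^2.}
#'
#' @param x Numeric values at which to evaluate the basis.
#' @param knots Strictly increasing numeric vector of at least 3 knots,
#'   typically from [rcs_knots()].
#' @param prefix Column-name prefix; columns are named `prefix`, `prefix'`,
#'   `prefix''`, ... following the usual spline-term convention.
#' @return Numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns.
#' @export
rcs_basis <- function(x, knots, prefix = "x") {
  stopifnot(is.numeric(x), is.numeric(knots), length(knots) >= 3,
            all(diff(knots) > 0))
  k <- length(knots)
  norm2 <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  cols <- vector("list", k - 1)
  cols[[1]] <- x
  for (j in seq_len(k - 2)) {
    cols[[j + 1]] <- (pos3(x - knots[j]) -
      pos3(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
      pos3(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])) /
      norm2
  }
  m <- do.call(cbind, cols)
  colnames(m) <- paste0(prefix, strrep("'", seq_len(k - 1) - 1))
  m
}
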