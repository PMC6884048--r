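# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (fine grids, exhaustive pair enumeration, textbook
# formulas) so they share no code path with the implementation they check.

# Trapezoid integration of max(0, interpolated PaO2 - threshold) on a fine
# grid, honouring the 12-h gap rule and window truncation.
riemann_auc <- function(bg, window_h, threshold_kpa = 13.3,
                        gap_limit_h = 12, dt = 0.001) {
  bg <- bg[order(bg$t_h), ]
  bg <- bg[bg$t_h >= 0, ]
  n <- nrow(bg)
  if (n < 2) return(0)
  total <- 0
  for (i in seq_len(n - 1)) {
    t0 <- bg$t_h[i]
    t1 <- bg$t_h[i + 1]
    if (t1 - t0 > gap_limit_h || t0 >= window_h) next
    hi <- min(t1, window_h)
    ts <- seq(t0, hi, length.out = max(2L, ceiling((hi - t0) / dt) + 1L))
    f <- bg$pao2_kpa[i] +
      (bg$pao2_kpa[i + 1] - bg$pao2_kpa[i]) * (ts - t0) / (t1 - t0)
    g <- pmax(f - threshold_kpa, 0)
    total <- total + sum((g[-1] + g[-length(g)]) / 2 * diff(ts))
  }
  total
}

# A random irregular blood-gas series; gaps straddle the 12-h rule.
random_series <- function(n_samples = sample(4:40, 1), id = "e1") {
  tibble::tibble(
    episode_id = id,
    t_h = cumsum(stats::runif(n_samples, 0.2, 16)),
    pao2_kpa = stats::runif(n_samples, 6, 25)
  )
}

# Exhaustive pair enumeration of the concordance probability.
brute_c_index <- function(p, y) {
  cases <- p[y == 1]
  ctrls <- p[y == 0]
  s <- 0
  for (a in cases) {
    for (b in ctrls) s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(cases) * length(ctrls))
}

# Threshold sweep for average precision, one explicit threshold at a time.
brute_average_precision <- function(p, y) {
  th <- sort(unique(p), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in th) {
    sel <- p >= t
    prec <- sum(y[sel]) / sum(sel)
    rec <- sum(y[sel]) / sum(y)
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

# Direct transcription of the restricted-cubic-spline truncated-power
# formula from the regression-modelling literature.
rcs_textbook <- function(x, knots) {
  k <- length(knots)
  tau <- (knots[k] - knots[1])^2
  sapply(seq_len(k - 2), function(j) {
    (pmax(x - knots[j], 0)^3 -
       pmax(x - knots[k - 1], 0)^3 *
         (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
       pmax(x - knots[k], 0)^3 *
         (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])) / tau
  })
}

# Small logistic design + outcome for model tests.
sim_logit_data <- function(n, beta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(beta) - 1
  x <- cbind(1, matrix(stats::rnorm(n * p), n, p))
  colnames(x) <- c("(Intercept)", paste0("x", seq_len(p)))
  y <- as.numeric(stats::runif(n) < stats::plogis(drop(x %*% beta)))
  list(x = x, y = y)
}

# Small synthetic window cohort reused by model-level tests.
test_cohort <- function(n = 4000, seed = 99, windows = 24, ...) {
  cfg <- cohort_config(n_patients = n, seed = seed, ...)
  co <- simulate_cohort(cfg)
  cohort <- apply_exclusions(co$admissions)
  build_nested_cohorts(cohort, co$blood_gas, co$ventilation,
                       windows = windows)
}
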