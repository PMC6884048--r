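#' Configuration for the synthetic ICU cohort generator
#'
#' Fully specifies the data-generating model behind [simulate_cohort()]:
#' patient covariates drawn to resemble a mixed medical/surgical adult ICU
#' population, a log-normal length of stay whose location shifts with
#' illness severity (sicker patients stay longer), irregular blood-gas
#' sampling with occasional long (> 12 h) gaps, a latent PaO2 level that is
#' constant per patient plus per-sample noise, a never-hyperoxemic subgroup
#' whose PaO2 stays below the threshold (the spike at zero), and ICU
#' mortality drawn from a logistic model on the *computed* hyperoxemia dose
#' over `outcome_window_h` hours plus the covariates. Death occurs at ICU
#' discharge.
#'
#' @param n_patients Number of ICU episodes to generate (one per patient
#'   plus a small fraction of flagged readmissions).
#' @param seed Integer seed; the same configuration yields byte-identical
#'   tables.
#' @param los_meanlog,los_sdlog Log-normal length of stay in days at average
#'   severity; defaults target a median stay of about 3.5 days.
#' @param los_apache_gamma Shift of `los_meanlog` per standard deviation of
#'   APACHE II above its mean.
#' @param gap_meanlog,gap_sdlog Log-normal inter-sample gap in hours
#'   (median about 3 h), capped at 12 h: routine monitoring never pauses
#'   longer than the interpolation limit, so gaps beyond it arise only via
#'   `p_long_gap`.
#' @param p_long_gap Probability that a gap is drawn instead from
#'   `long_gap_range` (a gap longer than the 12-h interpolation limit).
#' @param long_gap_range Range (hours) of the long gaps.
#' @param p_never_hyperoxemic Fraction of patients whose PaO2 is constrained
#'   below the threshold for their entire stay (the spike at zero).
#' @param p_exposed_from_admission Among hyperoxemia-capable patients, the
#'   probability that the hyperoxemic phase starts at ICU admission; the
#'   remainder start at a random time during the stay, drawn with an
#'   early-stay bias (squared-uniform fraction of the stay, since oxygen
#'   exposure is typically admission-associated). Late onsets are what make
#'   exposure prevalence grow with longer observation windows.
#' @param threshold_kpa Hyperoxemia boundary, default 13.3 kPa.
#' @param pao2_offset_shape,pao2_offset_scale Gamma(shape, scale) offset of
#'   the mean PaO2 above the threshold during the hyperoxemic phase.
#' @param pao2_sample_sd Per-sample Gaussian noise SD (kPa); samples are
#'   clamped to `[4, 60]` kPa, and to just below the threshold outside the
#'   hyperoxemic phase (supraphysiologic values require supplemental
#'   oxygen).
#' @param outcome_window_h Window (hours) over which the "true" dose that
#'   drives mortality is computed, using the package's own exposure engine
#'   on the generated samples.
#' @param true_coefficients Named list of log-odds for the mortality model:
#'   `intercept`, `any_exposure`, `dose` (per kPa), `respiratory_dx`,
#'   `sex_male`, `prior_dependency`, `medical`, `continuous_mv`, `age` (per
#'   year, centred at 65), `weight` (per kg, centred at 77), `apache` (per
#'   point, centred at 15.4).
#' @param p_respiratory_dx,p_prior_dependency,p_medical,p_male Covariate
#'   prevalences.
#' @param p_readmission,p_treatment_limitation,p_cpr,p_qc_fail,p_minor,
#'   p_missing_weight Rates of the administrative flags that exercise the
#'   exclusion criteria and the (< 1%) covariate missingness.
#' @return A list of class `oxy_config`.
#' @export
cohort_config <- function(
    n_patients = 20000,
    seed = 2014L,
    los_meanlog = log(3.5), los_sdlog = 0.85, los_apache_gamma = 0.65,
    gap_meanlog = log(3), gap_sdlog = 0.45,
    p_long_gap = 0.04, long_gap_range = c(13, 30),
    p_never_hyperoxemic = 0.08,
    p_exposed_from_admission = 0.6,
    threshold_kpa = 13.3,
    pao2_offset_shape = 2, pao2_offset_scale = 0.9,
    pao2_sample_sd = 1.3,
    outcome_window_h = 24,
    true_coefficients = list(
      intercept = -3.95,
      any_exposure = log(1.15),
      dose = 0,
      respiratory_dx = 0.30,
      sex_male = -0.05,
      prior_dependency = 0.40,
      medical = 0.50,
      continuous_mv = 0.40,
      age = 0.015,
      weight = 0,
      apache = 0.12
    ),
    p_respiratory_dx = 0.25, p_prior_dependency = 0.171,
    p_medical = 0.452, p_male = 0.60,
    p_readmission = 0.05, p_treatment_limitation = 0.03,
    p_cpr = 0.02, p_qc_fail = 0.01, p_minor = 0.01,
    p_missing_weight = 0.004) {
  cfg <- as.list(environment())
  probs <- cfg[grep("^p_", names(cfg))]
  if (cfg$n_patients < 1) rlang::abort("n_patients must be >= 1")
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    rlang::abort("probabilities must lie in [0, 1]")
  }
  if (cfg$threshold_kpa <= 0 || cfg$pao2_offset_scale <= 0 ||
      cfg$pao2_sample_sd <= 0 || cfg$gap_sdlog <= 0 || cfg$los_sdlog <= 0) {
    rlang::abort("distribution parameters must be positive")
  }
  need_coef <- c("intercept", "any_exposure", "dose", "respiratory_dx",
                 "sex_male", "prior_dependency", "medical", "continuous_mv",
                 "age", "weight", "apache")
  miss <- setdiff(need_coef, names(cfg$true_coefficients))
  if (length(miss) > 0) {
    rlang::abort(paste0("true_coefficients is missing: ",
                        paste(miss, collapse = ", ")))
  }
  structure(cfg, class = "oxy_config")
}

#' Generate a synthetic ICU cohort
#'
#' Draws admissions, blood-gas and ventilation tables from the
#' data-generating model described in [cohort_config()]. The mortality
#' outcome is a Bernoulli draw from a logistic model whose exposure inputs
#' (dose, any-exposure, continuous ventilation) are computed from the
#' generated data with the package's own exposure engine over
#' `outcome_window_h`, so downstream parameter-recovery checks are not
#' confounded by imputation error.
#'
#' @param config An [cohort_config()] object.
#' @return A list of class `oxy_cohort`: `admissions`, `blood_gas`,
#'   `ventilation` tibbles plus `truth` (per-episode true dose, exposure
#'   flag, linear predictor and death probability) and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "oxy_config"))
  cfg <- config
  withr::local_seed(cfg$seed)
  n <- cfg$n_patients

  episode_id <- sprintf("ep%06d", seq_len(n))
  age <- round(pmin(pmax(stats::rnorm(n, 62, 16), 18), 95), 1)
  minor <- stats::runif(n) < cfg$p_minor
  age[minor] <- round(stats::runif(sum(minor), 16, 17.9), 1)
  weight <- round(pmin(pmax(stats::rnorm(n, 77, 20), 35), 180), 1)
  sex <- ifelse(stats::runif(n) < cfg$p_male, "M", "F")
  apache <- as.integer(round(pmin(pmax(stats::rnorm(n, 15.4, 5.8), 0), 50)))
  respiratory_dx <- stats::runif(n) < cfg$p_respiratory_dx
  prior_dependency <- stats::runif(n) < cfg$p_prior_dependency
  patient_type <- ifelse(stats::runif(n) < cfg$p_medical, "medical", "surgical")

  los_meanlog <- cfg$los_meanlog +
    cfg$los_apache_gamma * (apache - 15.4) / 5.8
  los_h <- round(stats::rlnorm(n, los_meanlog, cfg$los_sdlog) * 24, 1)
  los_h <- pmax(los_h, 0.5)

  admission_seq <- 1L + as.integer(stats::runif(n) < cfg$p_readmission)
  treatment_limitation <- stats::runif(n) < cfg$p_treatment_limitation
  cpr_pre_24h <- stats::runif(n) < cfg$p_cpr
  qc_fail <- stats::runif(n) < cfg$p_qc_fail

  never <- stats::runif(n) < cfg$p_never_hyperoxemic
  # two-piece latent trajectory: a sub-threshold baseline mean, switching to
  # a hyperoxemic mean at a per-patient onset time (Inf = never)
  base_mean <- pmax(
    cfg$threshold_kpa - 1 - stats::rgamma(n, shape = 2, scale = 0.8), 5
  )
  hyper_mean <- cfg$threshold_kpa + 0.2 +
    stats::rgamma(n, shape = cfg$pao2_offset_shape,
                  scale = cfg$pao2_offset_scale)
  onset_h <- ifelse(stats::runif(n) < cfg$p_exposed_from_admission,
                    0, stats::runif(n)^2 * los_h)
  onset_h[never] <- Inf

  blood_gas <- simulate_blood_gas_table(episode_id, los_h, base_mean,
                                        hyper_mean, onset_h, cfg)
  ventilation <- simulate_ventilation(episode_id, los_h)

  truth_exp <- compute_exposure(
    blood_gas, window_h = cfg$outcome_window_h,
    threshold_kpa = cfg$threshold_kpa, episodes = episode_id
  )
  cmv <- derive_window_covariables(ventilation, episode_id,
                                   cfg$outcome_window_h)
  full_exp <- compute_exposure(
    blood_gas, window_h = max(los_h) + 1,
    threshold_kpa = cfg$threshold_kpa, episodes = episode_id
  )
  ever_exposed <- full_exp$any_exposure

  covariates <- tibble::tibble(
    respiratory_dx = respiratory_dx,
    sex_male = sex == "M",
    prior_dependency = prior_dependency,
    medical = patient_type == "medical",
    continuous_mv = cmv$continuous_mv,
    age_years = age,
    weight_kg = weight,
    apache_ii = apache
  )
  death <- simulate_outcome(
    true_dose = truth_exp$dose_kpa,
    any_exposure = truth_exp$any_exposure,
    covariates = covariates,
    coefficients = cfg$true_coefficients
  )

  weight_out <- weight
  miss_w <- stats::runif(n) < cfg$p_missing_weight
  weight_out[miss_w] <- NA_real_

  admissions <- tibble::tibble(
    patient_id = sprintf("pt%06d", seq_len(n)),
    episode_id = episode_id,
    admission_seq = admission_seq,
    age_years = age,
    weight_kg = weight_out,
    sex = sex,
    apache_ii = apache,
    respiratory_dx = respiratory_dx,
    prior_dependency = prior_dependency,
    patient_type = patient_type,
    treatment_limitation = treatment_limitation,
    cpr_pre_24h = cpr_pre_24h,
    qc_fail = qc_fail,
    los_h = los_h,
    icu_death = death$icu_death
  )

  structure(
    list(
      admissions = admissions,
      blood_gas = blood_gas,
      ventilation = ventilation,
      truth = tibble::tibble(
        episode_id = episode_id,
        never_hyperoxemic = never,
        onset_h = onset_h,
        base_mean_kpa = base_mean,
        hyper_mean_kpa = hyper_mean,
        ever_exposed = ever_exposed,
        true_dose_kpa = truth_exp$dose_kpa,
        true_any_exposure = truth_exp$any_exposure,
        linear_predictor = death$linear_predictor,
        death_probability = death$probability
      ),
      config = cfg
    ),
    class = "oxy_cohort"
  )
}

# Vectorised irregular sampling: gaps are drawn in bulk per episode and
# accumulated with a grouped cumulative sum; samples beyond discharge are
# discarded. Episodes too short for their first gap yield an empty series.
# PaO2 follows the sub-threshold baseline mean before the episode's onset
# time and the hyperoxemic mean after it; pre-onset samples are capped just
# below the threshold.
simulate_blood_gas_table <- function(episode_id, los_h, base_mean,
                                     hyper_mean, onset_h, cfg) {
  n <- length(episode_id)
  # enough draws that running past discharge before exhausting them is
  # essentially impossible (gap >= ~1.2 h with overwhelming probability)
  k <- pmax(8L, ceiling(los_h / 1.1) + 8L)
  total <- sum(k)
  is_long <- stats::runif(total) < cfg$p_long_gap
  gaps <- pmin(stats::rlnorm(total, cfg$gap_meanlog, cfg$gap_sdlog), 12)
  gaps[is_long] <- stats::runif(sum(is_long), cfg$long_gap_range[1],
                                cfg$long_gap_range[2])
  ep_idx <- rep.int(seq_len(n), k)
  cum <- cumsum(gaps)
  ends <- cumsum(k)
  offset <- c(0, cum[ends[-n]])
  t_h <- cum - offset[ep_idx]
  keep <- t_h <= los_h[ep_idx]
  ep_idx <- ep_idx[keep]
  t_h <- t_h[keep]
  hyper <- t_h >= onset_h[ep_idx]
  mean_kpa <- ifelse(hyper, hyper_mean[ep_idx], base_mean[ep_idx])
  pao2 <- pmin(pmax(mean_kpa + stats::rnorm(length(t_h), 0,
                                            cfg$pao2_sample_sd),
                    4), 60)
  pao2[!hyper] <- pmin(pao2[!hyper], cfg$threshold_kpa - 0.05)
  tibble::tibble(
    episode_id = episode_id[ep_idx],
    t_h = t_h,
    pao2_kpa = round(pao2, 2)
  )
}

# 0-2 ventilation intervals per episode, all within [0, los_h]
simulate_ventilation <- function(episode_id, los_h) {
  n <- length(episode_id)
  has1 <- stats::runif(n) < 0.65
  end1 <- stats::runif(n, 0.35, 1) * los_h
  has2 <- has1 & stats::runif(n) < 0.15 & end1 < 0.9 * los_h
  start2 <- end1 + stats::runif(n) * (los_h - end1) * 0.5
  end2 <- start2 + stats::runif(n) * (los_h - start2)
  v1 <- tibble::tibble(episode_id = episode_id[has1], start_h = 0,
                       end_h = round(end1[has1], 1))
  v2 <- tibble::tibble(episode_id = episode_id[has2],
                       start_h = round(start2[has2], 1),
                       end_h = round(pmin(end2[has2], los_h[has2]), 1))
  out <- dplyr::bind_rows(v1, v2)
  out[out$end_h > out$start_h, ]
}

#' Draw ICU death from the true mortality model
#'
#' Bernoulli mortality with probability `plogis(lp)` where the linear
#' predictor combines the intercept, the exposure terms (any-exposure
#' indicator and dose in kPa) and the covariates, with continuous
#' covariates centred at age 65 years, weight 77 kg and APACHE II 15.4.
#'
#' @param true_dose Hyperoxemia dose in kPa.
#' @param any_exposure Logical any-exposure indicator.
#' @param covariates Tibble with logical `respiratory_dx`, `sex_male`,
#'   `prior_dependency`, `medical`, `continuous_mv` and numeric
#'   `age_years`, `weight_kg`, `apache_ii` (missing weights are treated as
#'   the centring value, 77 kg).
#' @param coefficients Named list of log-odds; see [cohort_config()].
#' @return A list with `icu_death` (logical), `probability`, and
#'   `linear_predictor`.
#' @export
simulate_outcome <- function(true_dose, any_exposure, covariates,
                             coefficients) {
  need <- c("intercept", "any_exposure", "dose", "respiratory_dx",
            "sex_male", "prior_dependency", "medical", "continuous_mv",
            "age", "weight", "apache")
  miss <- setdiff(need, names(coefficients))
  if (length(miss) > 0) {
    rlang::abort(paste0("missing coefficient(s): ",
                        paste(miss, collapse = ", ")))
  }
  b <- coefficients
  w <- dplyr::coalesce(covariates$weight_kg, 77)
  lp <- b$intercept +
    b$any_exposure * as.numeric(any_exposure) +
    b$dose * true_dose +
    b$respiratory_dx * as.numeric(covariates$respiratory_dx) +
    b$sex_male * as.numeric(covariates$sex_male) +
    b$prior_dependency * as.numeric(covariates$prior_dependency) +
    b$medical * as.numeric(covariates$medical) +
    b$continuous_mv * as.numeric(covariates$continuous_mv) +
    b$age * (covariates$age_years - 65) +
    b$weight * (w - 77) +
    b$apache * (covariates$apache_ii - 15.4)
  p <- stats::plogis(lp)
  list(
    icu_death = stats::runif(length(lp)) < p,
    probability = p,
    linear_predictor = lp
  )
}

#' @export
print.oxy_cohort <- function(x, ...) {
  cat("<oxy_cohort> ", nrow(x$admissions), " episodes, ",
      nrow(x$blood_gas), " blood-gas samples (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}
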