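#' Apply study inclusion and exclusion criteria
#'
#' Retains adult (age >= 18) index admissions (`admission_seq == 1`) with an
#' ICU length of stay strictly longer than 24 hours, no treatment-limitation
#' order, no cardiopulmonary resuscitation in the 24 hours before admission,
#' passing data-quality checks, and with complete model covariates
#' (complete-case analysis). Each excluded episode is attributed to the
#' *first* failing criterion in the fixed order age, length of stay,
#' treatment limitation, CPR, quality checks, readmission, missing
#' covariates, giving a CONSORT-style accounting that partitions the input.
#'
#' @param admissions Admissions table: one row per ICU episode with columns
#'   `patient_id`, `episode_id`, `admission_seq`, `age_years`, `weight_kg`,
#'   `sex`, `apache_ii`, `respiratory_dx`, `prior_dependency`,
#'   `patient_type`, `treatment_limitation`, `cpr_pre_24h`, `qc_fail`,
#'   `los_h`, `icu_death`.
#' @return The retained rows as a tibble, with the per-criterion exclusion
#'   counts attached as attribute `"exclusions"` (see [exclusion_log()]).
#' @export
apply_exclusions <- function(admissions) {
  need <- c("patient_id", "episode_id", "admission_seq", "age_years",
            "weight_kg", "sex", "apache_ii", "respiratory_dx",
            "prior_dependency", "patient_type", "treatment_limitation",
            "cpr_pre_24h", "qc_fail", "los_h", "icu_death")
  miss <- setdiff(need, names(admissions))
  if (length(miss) > 0) {
    rlang::abort(paste0("admissions is missing required column(s): ",
                        paste(miss, collapse = ", ")))
  }
  covar_cols <- c("age_years", "weight_kg", "sex", "apache_ii",
                  "respiratory_dx", "prior_dependency", "patient_type",
                  "los_h", "icu_death")
  missing_covar <- Reduce(`|`, lapply(admissions[covar_cols], is.na))

  reason <- dplyr::case_when(
    !is.na(admissions$age_years) & admissions$age_years < 18 ~ "age_under_18",
    !is.na(admissions$los_h) & admissions$los_h <= 24 ~ "los_24h_or_less",
    isTRUE_vec(admissions$treatment_limitation) ~ "treatment_limitation",
    isTRUE_vec(admissions$cpr_pre_24h) ~ "cpr_pre_24h",
    isTRUE_vec(admissions$qc_fail) ~ "qc_fail",
    admissions$admission_seq > 1 ~ "readmission",
    missing_covar ~ "missing_covariates",
    .default = NA_character_
  )
  kept <- tibble::as_tibble(admissions[is.na(reason), ])
  criteria <- c("age_under_18", "los_24h_or_less", "treatment_limitation",
                "cpr_pre_24h", "qc_fail", "readmission", "missing_covariates")
  log <- tibble::tibble(
    criterion = c(criteria, "retained"),
    n = c(vapply(criteria, function(cr) sum(reason == cr, na.rm = TRUE),
                 integer(1)),
          nrow(kept))
  )
  attr(kept, "exclusions") <- log
  kept
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Per-criterion exclusion counts from [apply_exclusions()]
#'
#' @param cohort A tibble returned by [apply_exclusions()].
#' @return A tibble with columns `criterion` and `n`; the counts plus the
#'   retained row partition the input table.
#' @export
exclusion_log <- function(cohort) {
  log <- attr(cohort, "exclusions")
  if (is.null(log)) rlang::abort("no exclusion log attached; run apply_exclusions() first")
  log
}

#' Continuous mechanical ventilation over an exposure window
#'
#' An episode counts as continuously ventilated over `[0, window_h]` when the
#' union of its ventilation intervals covers the whole window with no
#' interior gap; intervals that touch end-to-start are merged (closed-interval
#' union), reflecting clinical continuity.
#'
#' @param ventilation Tibble with columns `episode_id`, `start_h`, `end_h`
#'   (hours since ICU admission); episodes may have zero, one or several
#'   intervals.
#' @param episodes Vector of episode ids to report on (episodes without
#'   ventilation rows are `FALSE`).
#' @param window_h Window length in hours.
#' @return A tibble with `episode_id` and logical `continuous_mv`.
#' @export
derive_window_covariables <- function(ventilation, episodes, window_h) {
  stopifnot(window_h > 0)
  if (is.null(ventilation) || nrow(ventilation) == 0) {
    return(tibble::tibble(episode_id = episodes, continuous_mv = FALSE))
  }
  need <- c("episode_id", "start_h", "end_h")
  miss <- setdiff(need, names(ventilation))
  if (length(miss) > 0) {
    rlang::abort(paste0("ventilation is missing required column(s): ",
                        paste(miss, collapse = ", ")))
  }
  cov <- ventilation |>
    dplyr::filter(.data$episode_id %in% episodes) |>
    dplyr::summarise(
      continuous_mv = covers_window(.data$start_h, .data$end_h, window_h),
      .by = "episode_id"
    )
  tibble::tibble(episode_id = episodes) |>
    dplyr::left_join(cov, by = "episode_id") |>
    dplyr::mutate(continuous_mv = dplyr::coalesce(.data$continuous_mv, FALSE))
}

# closed-interval union coverage of [0, w]
covers_window <- function(start_h, end_h, w) {
  o <- order(start_h)
  s <- start_h[o]
  e <- end_h[o]
  if (s[1] > 0) return(FALSE)
  reach <- e[1]
  for (i in seq_along(s)[-1]) {
    if (reach >= w) return(TRUE)
    if (s[i] > reach) return(FALSE) # interior gap
    reach <- max(reach, e[i])
  }
  reach >= w
}

#' Build nested censoring-free window cohorts
#'
#' For each exposure window `w`, keeps the episodes whose ICU stay spans the
#' whole window (`los_h >= w`), so the window's exposure cannot be cut short
#' by discharge or death (no informative censoring), then attaches the
#' window-specific exposure summary and the continuous-ventilation covariate.
#' Longer-window cohorts are by construction subsets of shorter-window ones.
#'
#' @param cohort Admissions already filtered by [apply_exclusions()].
#' @param blood_gas Blood-gas table (`episode_id`, `t_h`, `pao2_kpa`).
#' @param ventilation Optional ventilation-interval table; see
#'   [derive_window_covariables()].
#' @param windows Window lengths in hours, default `c(24, 72, 120, 168)`.
#' @param threshold_kpa,gap_limit_h Passed to [compute_exposure()].
#' @return A tibble in long format: the cohort columns plus `window_h`,
#'   `auc_kpa_h`, `dose_kpa`, `any_exposure`, `threshold_kpa`,
#'   `continuous_mv`, one row per episode and window it belongs to.
#' @export
build_nested_cohorts <- function(cohort, blood_gas, ventilation = NULL,
                                 windows = c(24, 72, 120, 168),
                                 threshold_kpa = 13.3, gap_limit_h = 12) {
  stopifnot(all(windows > 0))
  windows <- sort(unique(windows))
  purrr::map(windows, function(w) {
    sub <- dplyr::filter(cohort, .data$los_h >= w)
    if (nrow(sub) == 0) {
      return(dplyr::mutate(sub, window_h = numeric(0)))
    }
    expo <- compute_exposure(
      dplyr::semi_join(blood_gas, sub, by = "episode_id"),
      window_h = w, threshold_kpa = threshold_kpa,
      gap_limit_h = gap_limit_h, episodes = sub$episode_id
    )
    cmv <- derive_window_covariables(ventilation, sub$episode_id, w)
    sub |>
      dplyr::left_join(expo, by = "episode_id") |>
      dplyr::left_join(cmv, by = "episode_id")
  }) |>
    purrr::list_rbind()
}
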