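admissions_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    episode_id = readr::col_character(),
    admission_seq = readr::col_integer(),
    age_years = readr::col_double(),
    weight_kg = readr::col_double(),
    sex = readr::col_character(),
    apache_ii = readr::col_integer(),
    respiratory_dx = readr::col_logical(),
    prior_dependency = readr::col_logical(),
    patient_type = readr::col_character(),
    treatment_limitation = readr::col_logical(),
    cpr_pre_24h = readr::col_logical(),
    qc_fail = readr::col_logical(),
    los_h = readr::col_double(),
    icu_death = readr::col_logical()
  )
}

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    rlang::abort(paste0(what, " is missing required column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "oxydose_schema_error")
  }
  invisible(df)
}

#' Read an admissions table from CSV
#'
#' Loads and type-checks the one-row-per-episode admissions schema (see
#' [apply_exclusions()] for the column list). A missing required column is a
#' schema error naming the column; rows failing type validation are removed
#' and collected in the `"rejects"` attribute rather than aborting the load.
#'
#' @param path Path to `admissions.csv`.
#' @return A typed tibble with attribute `"rejects"` (tibble of dropped
#'   rows, zero rows when the file is clean).
#' @export
read_admissions <- function(path) {
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = admissions_col_types())
  )
  check_columns(raw, names(admissions_col_types()$cols), "admissions")
  bad <- is.na(raw$episode_id) | is.na(raw$los_h) | is.na(raw$admission_seq)
  out <- raw[!bad, ]
  attr(out, "rejects") <- raw[bad, ]
  out
}

#' Read a blood-gas table from CSV
#'
#' Loads the per-sample schema (`episode_id`, `t_h`, `pao2_kpa`). Rows with
#' non-numeric or missing times or PaO2 values are rejected individually;
#' valid rows proceed.
#'
#' @param path Path to `blood_gas.csv`.
#' @return A typed tibble with attribute `"rejects"`.
#' @export
read_blood_gas <- function(path) {
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      episode_id = readr::col_character(),
      t_h = readr::col_double(),
      pao2_kpa = readr::col_double()
    )
  ))
  check_columns(raw, c("episode_id", "t_h", "pao2_kpa"), "blood_gas")
  bad <- is.na(raw$episode_id) | is.na(raw$t_h) | is.na(raw$pao2_kpa) |
    raw$pao2_kpa <= 0
  out <- raw[!bad, ]
  attr(out, "rejects") <- raw[bad, ]
  out
}

#' Read a ventilation-interval table from CSV
#'
#' @param path Path to `ventilation.csv` (`episode_id`, `start_h`, `end_h`).
#' @return A typed tibble with attribute `"rejects"`.
#' @export
read_ventilation <- function(path) {
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      episode_id = readr::col_character(),
      start_h = readr::col_double(),
      end_h = readr::col_double()
    )
  ))
  check_columns(raw, c("episode_id", "start_h", "end_h"), "ventilation")
  bad <- is.na(raw$episode_id) | is.na(raw$start_h) | is.na(raw$end_h) |
    raw$end_h <= raw$start_h
  out <- raw[!bad, ]
  attr(out, "rejects") <- raw[bad, ]
  out
}

#' Write the tables of a synthetic cohort to CSV
#'
#' @param cohort An `oxy_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "oxy_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("admissions.csv", "blood_gas.csv",
                            "ventilation.csv"))
  readr::write_csv(cohort$admissions, paths[1])
  readr::write_csv(cohort$blood_gas, paths[2])
  readr::write_csv(cohort$ventilation, paths[3])
  invisible(paths)
}

#' Run the full hyperoxemia-dose analysis pipeline
#'
#' Orchestrates the complete analysis on one admissions/blood-gas/
#' ventilation extract: exclusions, nested censoring-free window cohorts
#' with window-specific exposure, one mortality model per window, a
#' Table-2-style odds-ratio summary for the two exposure terms, bootstrap
#' optimism-corrected validation, and the counterfactual zero-exposure
#' average treatment effect. All randomness (the bootstrap) descends from
#' `seed`, so two runs with the same inputs and configuration are
#' identical.
#'
#' @param admissions,blood_gas,ventilation Input tables (see
#'   [read_admissions()] and friends, or [simulate_cohort()]).
#' @param windows Exposure windows in hours, default `c(24, 72, 120, 168)`.
#' @param threshold_kpa,gap_limit_h Exposure-engine settings.
#' @param link,interactions,lambda,lambda_grid,n_knots Model settings; see
#'   [fit_outcome_model()].
#' @param B Bootstrap resamples for validation; set `B = 0` to skip
#'   validation.
#' @param seed Root seed for the bootstrap stages.
#' @param output_dir Optional directory; when given, per-window cohort and
#'   exposure CSVs, model JSONs, the odds-ratio summary, validation and ATE
#'   reports, the exclusion log and a run manifest are written there.
#' @return A list of class `oxy_pipeline`: `cohorts` (long tibble),
#'   `exclusions`, `fits`, `or_summary`, `validation`, `ate`, `manifest`.
#' @export
run_pipeline <- function(admissions, blood_gas, ventilation = NULL,
                         windows = c(24, 72, 120, 168),
                         threshold_kpa = 13.3, gap_limit_h = 12,
                         link = "logit", interactions = FALSE,
                         lambda = 0, lambda_grid = NULL, n_knots = 4,
                         B = 200, seed = 1L, output_dir = NULL) {
  stopifnot(length(windows) >= 1, all(windows > 0), B >= 0)
  windows <- sort(unique(windows))

  cohort <- apply_exclusions(admissions)
  excl <- exclusion_log(cohort)
  nested <- build_nested_cohorts(
    cohort, blood_gas, ventilation = ventilation, windows = windows,
    threshold_kpa = threshold_kpa, gap_limit_h = gap_limit_h
  )

  fits <- list()
  validation <- list()
  ate <- list()
  or_rows <- list()
  for (i in seq_along(windows)) {
    w <- windows[i]
    dat <- dplyr::filter(nested, .data$window_h == w)
    fit <- fit_outcome_model(
      dat, link = link, interactions = interactions, lambda = lambda,
      lambda_grid = lambda_grid, n_knots = n_knots
    )
    fits[[as.character(w)]] <- fit
    or_rows[[i]] <- dplyr::bind_rows(
      term_odds_ratio(fit, "dose_kpa"),
      term_odds_ratio(fit, "any_exposure")
    ) |>
      dplyr::mutate(window_h = w, .before = 1)
    if (B > 0) {
      validation[[as.character(w)]] <-
        bootstrap_validate(fit, B = B, seed = seed + i)
    }
    ate[[as.character(w)]] <- average_treatment_effect(fit)
  }
  or_summary <- purrr::list_rbind(or_rows)

  config <- list(
    windows = windows, threshold_kpa = threshold_kpa,
    gap_limit_h = gap_limit_h, link = link, interactions = interactions,
    lambda = lambda, lambda_grid = lambda_grid, n_knots = n_knots,
    B = B, seed = seed
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("oxydose")),
    config = config,
    config_hash = rlang::hash(config),
    n_input = nrow(admissions),
    n_retained = nrow(cohort),
    cohort_sizes = stats::setNames(
      as.list(vapply(windows,
                     function(w) sum(nested$window_h == w), numeric(1))),
      paste0("w", windows)
    )
  )

  out <- structure(
    list(cohorts = nested, exclusions = excl, fits = fits,
         or_summary = or_summary, validation = validation, ate = ate,
         manifest = manifest),
    class = "oxy_pipeline"
  )
  if (!is.null(output_dir)) write_pipeline(out, output_dir)
  out
}

write_pipeline <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (w in names(bundle$fits)) {
    dat <- dplyr::filter(bundle$cohorts, .data$window_h == as.numeric(w))
    readr::write_csv(dat, file.path(dir, paste0("cohort_", w, ".csv")))
    fit <- bundle$fits[[w]]
    jsonlite::write_json(
      list(
        link = fit$link, lambda = fit$lambda, n = fit$n,
        log_lik = fit$log_lik, edf = fit$edf, aic = fit$aic,
        converged = fit$converged,
        coefficients = as.list(fit$coefficients),
        knots = fit$meta$knots
      ),
      file.path(dir, paste0("model_", w, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    readr::write_csv(bundle$ate[[w]]$pairs,
                     file.path(dir, paste0("ate_pairs_", w, ".csv")))
    if (!is.null(bundle$validation[[w]])) {
      v <- bundle$validation[[w]]
      jsonlite::write_json(
        list(metrics = v$metrics, calibration = v$calibration,
             B = v$B, B_used = v$B_used, seed = v$seed),
        file.path(dir, paste0("validation_", w, ".json")),
        dataframe = "rows", auto_unbox = TRUE, digits = NA
      )
    }
  }
  readr::write_csv(bundle$or_summary, file.path(dir, "or_summary.csv"))
  jsonlite::write_json(
    purrr::transpose(bundle$exclusions),
    file.path(dir, "exclusions_log.json"), auto_unbox = TRUE
  )
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.oxy_pipeline <- function(x, ...) {
  cat("<oxy_pipeline> windows:",
      paste(names(x$fits), collapse = ", "), "h;",
      x$manifest$n_retained, "of", x$manifest$n_input, "episodes retained\n")
  print(x$or_summary)
  invisible(x)
}
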