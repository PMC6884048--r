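#' Linear imputation segments for a blood-gas series
#'
#' Arterial PaO2 is measured as a point process. To approximate a continuous
#' trajectory, consecutive samples are joined by straight lines, but only when
#' they are close enough in time to make interpolation defensible: pairs more
#' than `gap_limit_h` hours apart contribute no segment, and the interval
#' between them is treated as unobserved (zero exposure). Segments that cross
#' the end of the exposure window are truncated there by linear interpolation.
#'
#' @param blood_gas A data frame with columns `episode_id`, `t_h` (hours since
#'   ICU admission) and `pao2_kpa`. Times must be strictly increasing within
#'   an episode; samples taken before admission (`t_h < 0`) are discarded.
#' @param window_h Length of the exposure window in hours (e.g. 24, 72, 120,
#'   168).
#' @param gap_limit_h Maximum inter-sample gap, in hours, across which linear
#'   interpolation is performed. Default 12; gaps strictly greater than this
#'   yield no segment.
#'
#' @return A tibble with one row per retained segment: `episode_id`,
#'   `t_start_h`, `t_end_h`, `pao2_start_kpa`, `pao2_end_kpa`. Episodes with
#'   zero or one usable sample contribute no rows.
#' @export
#' @examples
#' bg <- tibble::tibble(
#'   episode_id = "e1",
#'   t_h = c(1, 14, 20, 30),
#'   pao2_kpa = c(15, 15, 16, 16)
#' )
#' build_segments(bg, window_h = 24) # 13-h gap dropped, last pair truncated
build_segments <- function(blood_gas, window_h, gap_limit_h = 12) {
  stopifnot(is.numeric(window_h), length(window_h) == 1, window_h > 0)
  check_blood_gas(blood_gas)

  bg <- dplyr::filter(blood_gas, .data$t_h >= 0)
  empty <- tibble::tibble(
    episode_id = bg$episode_id[0], t_start_h = numeric(),
    t_end_h = numeric(), pao2_start_kpa = numeric(),
    pao2_end_kpa = numeric()
  )
  n <- nrow(bg)
  if (n < 2) return(empty)

  o <- order(bg$episode_id, bg$t_h, method = "radix")
  ep <- bg$episode_id[o]
  tt <- bg$t_h[o]
  pp <- bg$pao2_kpa[o]

  # consecutive-sample pairs within the same episode, as flat vector shifts
  same <- ep[-n] == ep[-1]
  if (any(same & tt[-1] <= tt[-n])) {
    rlang::abort("blood_gas has non-increasing sample times within an episode")
  }
  t0 <- tt[-n]
  t1 <- tt[-1]
  p0 <- pp[-n]
  p1 <- pp[-1]
  keep <- same & (t1 - t0 <= gap_limit_h) & (t0 < window_h)
  if (!any(keep)) return(empty)
  ep <- ep[-n][keep]
  t0 <- t0[keep]
  t1 <- t1[keep]
  p0 <- p0[keep]
  p1 <- p1[keep]

  # truncate segments that straddle the window boundary
  over <- t1 > window_h
  if (any(over)) {
    frac <- (window_h - t0[over]) / (t1[over] - t0[over])
    p1[over] <- p0[over] + frac * (p1[over] - p0[over])
    t1[over] <- window_h
  }
  tibble::tibble(
    episode_id = ep, t_start_h = t0, t_end_h = t1,
    pao2_start_kpa = p0, pao2_end_kpa = p1
  )
}

#' Area of a linear PaO2 segment above the hyperoxemia threshold
#'
#' Closed-form area between a straight-line PaO2 segment and a horizontal
#' threshold, counting only the part of the segment above the threshold.
#' If both endpoints are at or below the threshold the area is zero; if both
#' are above, the area is a trapezoid; if the segment crosses the threshold,
#' it is the triangle cut off at the crossing point. Values exactly at the
#' threshold are not hyperoxemic and contribute nothing.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param pao2_start_kpa,pao2_end_kpa Endpoint PaO2 values (kPa).
#' @param t_start_h,t_end_h Endpoint times (hours).
#' @param threshold_kpa Hyperoxemia boundary, default 13.3 kPa (100 mm Hg).
#'
#' @return Numeric vector of areas in kPa·h, always `>= 0`.
#' @export
#' @examples
#' # trapezoid: both endpoints above threshold
#' segment_area_above_threshold(15, 17, 0, 2) # (1.7 + 3.7)/2 * 2 = 5.4
#' # triangle: crossing at t = 3.3 h
#' segment_area_above_threshold(10, 20, 0, 10) # 6.7^2 / 2 = 22.445
segment_area_above_threshold <- function(pao2_start_kpa, pao2_end_kpa,
                                         t_start_h, t_end_h,
                                         threshold_kpa = 13.3) {
  dt <- t_end_h - t_start_h
  a0 <- pao2_start_kpa - threshold_kpa
  a1 <- pao2_end_kpa - threshold_kpa
  area <- numeric(length(dt))

  both_above <- a0 > 0 & a1 > 0
  area[both_above] <- (a0[both_above] + a1[both_above]) / 2 * dt[both_above]

  down <- a0 > 0 & a1 <= 0
  area[down] <- 0.5 * a0[down]^2 / (a0[down] - a1[down]) * dt[down]

  up <- a0 <= 0 & a1 > 0
  area[up] <- 0.5 * a1[up]^2 / (a1[up] - a0[up]) * dt[up]

  area[dt <= 0] <- 0
  pmax(area, 0)
}

#' Window-specific hyperoxemia exposure summaries
#'
#' Computes, for each episode and each exposure window, the cumulative
#' hyperoxemia exposure (area of the interpolated PaO2 curve above the
#' threshold, in kPa·h), the hyperoxemia dose (that area divided by the full
#' window length, in kPa), and an any-exposure indicator. Time where PaO2 is
#' unobserved — before the first sample, after the last, or inside a gap
#' longer than `gap_limit_h` — counts as zero exposure, so the dose
#' denominator is always the full window. A dose of 1 kPa means the
#' patient's average PaO2 exceeded the threshold by 1 kPa for the whole
#' window.
#'
#' @inheritParams build_segments
#' @param window_h Vector of window lengths in hours; default
#'   `c(24, 72, 120, 168)` (days 0–1, 0–3, 0–5, 0–7).
#' @param threshold_kpa Hyperoxemia boundary in kPa, default 13.3.
#' @param episodes Optional vector of episode ids that must appear in the
#'   output; episodes with no usable samples get zero exposure. Defaults to
#'   the episodes present in `blood_gas`.
#'
#' @return A tibble with columns `episode_id`, `window_h`, `auc_kpa_h`,
#'   `dose_kpa`, `any_exposure`, `threshold_kpa`, one row per episode and
#'   window.
#' @export
#' @examples
#' bg <- tibble::tibble(episode_id = "e1", t_h = 0:24,
#'                      pao2_kpa = rep(14.3, 25))
#' compute_exposure(bg, window_h = 24) # dose exactly 1 kPa
compute_exposure <- function(blood_gas, window_h = c(24, 72, 120, 168),
                             threshold_kpa = 13.3, gap_limit_h = 12,
                             episodes = NULL) {
  stopifnot(is.numeric(window_h), length(window_h) >= 1, all(window_h > 0),
            threshold_kpa > 0, gap_limit_h > 0)
  check_blood_gas(blood_gas)
  if (is.null(episodes)) episodes <- unique(blood_gas$episode_id)

  purrr::map(sort(unique(window_h)), function(w) {
    seg <- build_segments(blood_gas, window_h = w, gap_limit_h = gap_limit_h)
    seg$area <- segment_area_above_threshold(
      seg$pao2_start_kpa, seg$pao2_end_kpa, seg$t_start_h, seg$t_end_h,
      threshold_kpa = threshold_kpa
    )
    sums <- rowsum(seg$area, seg$episode_id)
    auc <- tibble::tibble(episode_id = rownames(sums),
                          auc_kpa_h = as.numeric(sums))
    tibble::tibble(episode_id = episodes) |>
      dplyr::left_join(auc, by = "episode_id") |>
      dplyr::mutate(
        auc_kpa_h = dplyr::coalesce(.data$auc_kpa_h, 0),
        window_h = w,
        dose_kpa = .data$auc_kpa_h / w,
        any_exposure = .data$auc_kpa_h > 0,
        threshold_kpa = threshold_kpa
      ) |>
      dplyr::select("episode_id", "window_h", "auc_kpa_h", "dose_kpa",
                    "any_exposure", "threshold_kpa")
  }) |>
    purrr::list_rbind()
}

check_blood_gas <- function(blood_gas) {
  need <- c("episode_id", "t_h", "pao2_kpa")
  miss <- setdiff(need, names(blood_gas))
  if (length(miss) > 0) {
    rlang::abort(paste0("blood_gas is missing required column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (anyNA(blood_gas$t_h) || anyNA(blood_gas$pao2_kpa)) {
    rlang::abort("blood_gas contains missing t_h or pao2_kpa values")
  }
  invisible(blood_gas)
}
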