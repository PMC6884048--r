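#' Plot a blood-gas series with its hyperoxemia area
#'
#' Shows the observed PaO2 samples of one episode, the gap-aware linear
#' interpolation (segments are only drawn across gaps of at most
#' `gap_limit_h` hours), the hyperoxemia threshold, and the shaded area
#' above the threshold that makes up the cumulative exposure; the window
#' end is marked by a dashed vertical line.
#'
#' @inheritParams build_segments
#' @param episode One episode id present in `blood_gas`.
#' @param threshold_kpa Hyperoxemia boundary, default 13.3 kPa.
#' @return A ggplot object.
#' @export
plot_exposure <- function(blood_gas, episode, window_h = 24,
                          threshold_kpa = 13.3, gap_limit_h = 12) {
  bg <- dplyr::filter(blood_gas, .data$episode_id == episode,
                      .data$t_h <= window_h * 1.15)
  if (nrow(bg) == 0) rlang::abort("episode not found in blood_gas")
  seg <- build_segments(dplyr::filter(blood_gas, .data$episode_id == episode),
                        window_h = window_h, gap_limit_h = gap_limit_h)
  # polygon pieces above the threshold, one per segment
  ribbon <- purrr::pmap(seg, function(episode_id, t_start_h, t_end_h,
                                      pao2_start_kpa, pao2_end_kpa) {
    tt <- seq(t_start_h, t_end_h, length.out = 24)
    pp <- pao2_start_kpa + (pao2_end_kpa - pao2_start_kpa) *
      (tt - t_start_h) / max(t_end_h - t_start_h, 1e-12)
    tibble::tibble(t_h = tt, upper = pmax(pp, threshold_kpa),
                   piece = paste0(t_start_h))
  }) |> purrr::list_rbind()

  ggplot2::ggplot(bg, ggplot2::aes(x = .data$t_h, y = .data$pao2_kpa)) +
    ggplot2::geom_ribbon(
      data = ribbon,
      ggplot2::aes(x = .data$t_h, ymin = threshold_kpa, ymax = .data$upper,
                   group = .data$piece),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.45
    ) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$t_start_h, xend = .data$t_end_h,
                   y = .data$pao2_start_kpa, yend = .data$pao2_end_kpa),
      inherit.aes = FALSE, linetype = "21", linewidth = 0.3
    ) +
    ggplot2::geom_point(colour = "firebrick", size = 1.4) +
    ggplot2::geom_hline(yintercept = threshold_kpa, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = window_h, linetype = "dashed") +
    ggplot2::labs(
      x = "Hours since ICU admission",
      y = expression(Pa[O2] ~ "(kPa)"),
      title = paste0("Hyperoxemia exposure, episode ", episode,
                     ", ", window_h, "-h window")
    ) +
    ggplot2::theme_minimal()
}

#' Calibration plot for a bootstrap validation report
#'
#' Decile bins of predicted risk against observed mortality, the apparent
#' lowess calibration curve, the optimism-corrected (recalibrated) curve
#' and the ideal diagonal.
#'
#' @param object An `oxy_validation` from [bootstrap_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oxy_validation
#' @export
autoplot.oxy_validation <- function(object, ...) {
  sm <- object$smooth |>
    tidyr::pivot_longer(c("apparent", "corrected"),
                        names_to = "curve", values_to = "observed")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$predicted,
                                   y = .data$observed,
                                   linetype = .data$curve)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = object$calibration,
      ggplot2::aes(x = .data$pred_mean, y = .data$obs_rate),
      inherit.aes = FALSE, shape = 21, fill = "steelblue"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Predicted ICU mortality risk",
                  y = "Observed mortality",
                  linetype = NULL,
                  title = paste0("Bootstrap-corrected calibration (B = ",
                                 object$B, ")")) +
    ggplot2::theme_minimal()
}

#' Observed-versus-counterfactual risk plot
#'
#' Scatter of each episode's fitted mortality risk under its observed
#' hyperoxemia exposure against the counterfactual risk with exposure set
#' to zero. Unexposed episodes lie exactly on the identity line.
#'
#' @param object An `oxy_ate` from [average_treatment_effect()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oxy_ate
#' @export
autoplot.oxy_ate <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$risk_zero,
                               y = .data$risk_observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Counterfactual risk (exposure set to 0)",
      y = "Risk under observed exposure",
      title = paste0("Counterfactual mortality risk, ",
                     object$window_h, "-h window (ATE = ",
                     signif(object$ate_pp, 3), " pp)")
    ) +
    ggplot2::theme_minimal()
}
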