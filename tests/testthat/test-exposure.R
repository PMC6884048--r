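test_that("segment areas match hand-computed trapezoid and triangle cases", {
  # both endpoints above threshold: trapezoid (1.7 + 3.7)/2 * 2
  expect_equal(segment_area_above_threshold(15, 17, 0, 2), 5.4)
  # fully below the boundary
  expect_equal(segment_area_above_threshold(10, 12, 0, 7), 0)
  # crossing at t = 3.3 h: triangle 6.7^2 / 2
  expect_equal(segment_area_above_threshold(10, 20, 0, 10), 22.445)
  # descending crossing is symmetric
  expect_equal(segment_area_above_threshold(20, 10, 0, 10), 22.445)
  # exact threshold equality contributes nothing (boundary not hyperoxemic)
  expect_equal(segment_area_above_threshold(13.3, 13.3, 0, 5), 0)
  # zero-duration segment
  expect_equal(segment_area_above_threshold(20, 20, 3, 3), 0)
})

test_that("gap rule, boundary truncation and degenerate series behave as specified", {
  # 13-h gap: no interpolation across it
  bg <- tibble::tibble(episode_id = "e1", t_h = c(1, 14), pao2_kpa = c(15, 15))
  expect_equal(nrow(build_segments(bg, window_h = 24)), 0)
  # gap of exactly 12 h is still interpolated (strictly greater is excluded)
  bg12 <- tibble::tibble(episode_id = "e1", t_h = c(1, 13), pao2_kpa = c(15, 15))
  expect_equal(nrow(build_segments(bg12, window_h = 24)), 1)
  # segment straddling the window end is truncated at the boundary
  bg2 <- tibble::tibble(episode_id = "e1", t_h = c(20, 30), pao2_kpa = c(15, 15))
  seg <- build_segments(bg2, window_h = 24)
  expect_equal(seg$t_start_h, 20)
  expect_equal(seg$t_end_h, 24)
  # single sample yields no segments, and exposure falls back to zero
  bg3 <- tibble::tibble(episode_id = "e1", t_h = 5, pao2_kpa = 40)
  expect_equal(nrow(build_segments(bg3, window_h = 24)), 0)
  e <- compute_exposure(bg3, window_h = 24)
  expect_equal(e$dose_kpa, 0)
  expect_false(e$any_exposure)
  # pre-admission samples are discarded
  bg4 <- tibble::tibble(episode_id = "e1", t_h = c(-3, 1, 4),
                        pao2_kpa = c(50, 15, 15))
  expect_equal(nrow(build_segments(bg4, window_h = 24)), 1)
  # samples wholly after the window contribute nothing
  bg5 <- tibble::tibble(episode_id = "e1", t_h = c(25, 27), pao2_kpa = c(20, 20))
  expect_equal(compute_exposure(bg5, window_h = 24)$auc_kpa_h, 0)
})

test_that("worked dose examples reproduce the defining arithmetic", {
  # constant 14.3 kPa for the whole 24-h window: dose exactly 1 kPa
  bg <- tibble::tibble(episode_id = "e1", t_h = 0:24, pao2_kpa = rep(14.3, 25))
  expect_equal(compute_exposure(bg, window_h = 24)$dose_kpa, 1.0)
  # two-point crossing series: auc 22.445 kPa*h, dose 22.445/24
  bg2 <- tibble::tibble(episode_id = "e1", t_h = c(0, 10), pao2_kpa = c(10, 20))
  e <- compute_exposure(bg2, window_h = 24)
  expect_equal(e$auc_kpa_h, 22.445)
  expect_equal(round(e$dose_kpa, 4), 0.9352)
  # all samples at or below threshold: zero dose, unexposed
  bg3 <- tibble::tibble(episode_id = "e1", t_h = 0:10,
                        pao2_kpa = seq(8, 13.3, length.out = 11))
  e3 <- compute_exposure(bg3, window_h = 24)
  expect_equal(e3$dose_kpa, 0)
  expect_false(e3$any_exposure)
})

test_that("closed-form exposure equals fine-grid numeric integration", {
  set.seed(401)
  for (i in 1:25) {
    bg <- random_series()
    w <- sample(c(24, 72, 120, 168), 1)
    ours <- compute_exposure(bg, window_h = w)$auc_kpa_h
    expect_lt(abs(ours - riemann_auc(bg, w)), 1e-3)
  }
})

test_that("exposure is monotone in threshold and window and respects truncation", {
  set.seed(402)
  for (i in 1:20) {
    bg <- random_series(n_samples = 30)
    a_lo <- compute_exposure(bg, 72, threshold_kpa = 12)$auc_kpa_h
    a_hi <- compute_exposure(bg, 72, threshold_kpa = 16)$auc_kpa_h
    expect_gte(a_lo, a_hi)
    a_short <- compute_exposure(bg, 24)$auc_kpa_h
    a_long <- compute_exposure(bg, 168)$auc_kpa_h
    expect_gte(a_long, a_short)
    # dropping samples beyond the first one past the window changes nothing
    w <- 72
    first_after <- which(bg$t_h > w)[1]
    if (!is.na(first_after) && first_after < nrow(bg)) {
      expect_equal(compute_exposure(bg[seq_len(first_after), ], w)$auc_kpa_h,
                   compute_exposure(bg, w)$auc_kpa_h)
    }
  }
})

test_that("adding c to a fully covered supra-threshold series raises dose by c", {
  bg <- tibble::tibble(episode_id = "e1", t_h = seq(0, 26, by = 2),
                       pao2_kpa = 16 + sin(seq(0, 26, by = 2)))
  d0 <- compute_exposure(bg, window_h = 24)$dose_kpa
  d1 <- compute_exposure(dplyr::mutate(bg, pao2_kpa = pao2_kpa + 1.7),
                         window_h = 24)$dose_kpa
  expect_equal(d1 - d0, 1.7)
})

test_that("exposure bound and indicator identity hold on random series", {
  set.seed(403)
  for (i in 1:10) {
    bg <- random_series(n_samples = 25)
    e <- compute_exposure(bg, window_h = 72)
    expect_lte(e$auc_kpa_h, max(0, (max(bg$pao2_kpa) - 13.3)) * 72 + 1e-12)
    expect_identical(e$any_exposure, e$auc_kpa_h > 0)
  }
})

test_that("malformed blood-gas input is rejected with a clear error", {
  expect_error(compute_exposure(tibble::tibble(episode_id = "e", t_h = 1),
                                window_h = 24),
               "missing required column")
  dup <- tibble::tibble(episode_id = "e", t_h = c(1, 1), pao2_kpa = c(14, 15))
  expect_error(build_segments(dup, window_h = 24), "non-increasing")
})
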