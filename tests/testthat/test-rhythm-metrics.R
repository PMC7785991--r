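test_that("pp_intervals differences, count and errors behave", {
  iv <- pp_intervals(tibble::tibble(p_time_s = c(0, 0.5, 1.0)))
  expect_equal(iv$pp_s, c(0.5, 0.5))
  b <- tibble::tibble(p_time_s = cumsum(c(0, rep(0.522, 115))))
  expect_equal(nrow(pp_intervals(b)), 115)
  expect_error(pp_intervals(tibble::tibble(p_time_s = 1)), class = "zfecg_insufficient")
  expect_error(pp_intervals(tibble::tibble(p_time_s = c(1, 0.5))), class = "zfecg_input")
})

test_that("detected intervals match the simulator schedule (noiseless)", {
  rec <- simulate_ecg(noiseless(wt_config, duration_s = 20, seed = 5))
  beats <- detect_beats(rec$trace)
  iv_det <- pp_intervals(beats)$pp_s
  iv_true <- truth_intervals(rec$truth)$pp_s
  expect_equal(length(iv_det), length(iv_true))
  fs <- attr(rec$trace, "fs")
  expect_lt(max(abs(iv_det - iv_true)), 1 / fs + 1e-9)
})

test_that("compute_indices reports the defined quantities", {
  beats <- tibble::tibble(
    p_time_s = c(0, 0.52, 1.04, 1.56),
    p_amp_mV = 0.045,
    qrs_onset_s = c(0, 0.52, 1.04, 1.56) + 0.033,
    r_time_s = c(0, 0.52, 1.04, 1.56) + 0.06,
    r_amp_mV = 0.248,
    qrs_offset_s = c(0, 0.52, 1.04, 1.56) + 0.084,
    qrs_detected = TRUE
  )
  idx <- compute_indices(beats)
  expect_equal(idx$hr_bpm * idx$mean_pp_s, 60, tolerance = 1e-12)
  expect_equal(idx$hr_bpm, 60 / 0.52, tolerance = 1e-12)
  expect_equal(idx$sd_pp_s, 0)
  expect_equal(idx$p_over_r_ratio, 0.045 / 0.248, tolerance = 1e-12)
  expect_equal(idx$mean_pr_s, 0.033)
  expect_equal(idx$mean_qrs_s, 0.084 - 0.033)
  expect_equal(idx$qrs_detectability, 1)
})

test_that("QRS-dependent indices are absent (NA) without any detected QRS", {
  beats <- tibble::tibble(
    p_time_s = c(0, 0.5, 1.1), p_amp_mV = 0.05,
    qrs_onset_s = NA_real_, r_time_s = NA_real_, r_amp_mV = NA_real_,
    qrs_offset_s = NA_real_, qrs_detected = FALSE
  )
  idx <- compute_indices(beats)
  expect_true(is.na(idx$mean_r_amp_mV))
  expect_true(is.na(idx$p_over_r_ratio))
  expect_true(is.na(idx$mean_pr_s))
  expect_true(is.na(idx$mean_qrs_s))
  expect_equal(idx$qrs_detectability, 0)
})

test_that("sd_pp matches the definitional two-pass formula", {
  set.seed(99)
  x <- stats::rnorm(40, 0.5, 0.1)
  beats <- tibble::tibble(
    p_time_s = cumsum(c(0, abs(x))), p_amp_mV = 0.05,
    qrs_onset_s = NA_real_, r_time_s = NA_real_, r_amp_mV = NA_real_,
    qrs_offset_s = NA_real_, qrs_detected = FALSE
  )
  idx <- compute_indices(beats)
  pp <- diff(beats$p_time_s)
  expect_equal(idx$sd_pp_s, sqrt(sum((pp - mean(pp))^2) / (length(pp) - 1)),
               tolerance = 1e-12)
})

test_that("flag_long_beats applies the mean + 2 SD rule", {
  const <- pp_intervals(tibble::tibble(p_time_s = cumsum(c(0, rep(0.5, 10)))))
  expect_length(flag_long_beats(const), 0)
  iv <- pp_intervals(tibble::tibble(p_time_s = cumsum(c(0, rep(0.5, 19), 1.4))))
  expect_equal(flag_long_beats(iv), 20L)
  # flags are invariant under time-reversal (as a set of positions)
  rev_iv <- pp_intervals(tibble::tibble(p_time_s = cumsum(c(0, rev(iv$pp_s)))))
  n <- nrow(iv)
  expect_equal(sort(n + 1L - flag_long_beats(rev_iv)), sort(flag_long_beats(iv)))
  expect_error(flag_long_beats(pp_intervals(tibble::tibble(p_time_s = c(0, 0.5)))),
               class = "zfecg_insufficient")
})

test_that("classify_ecg follows the detectability and amplitude criteria", {
  mk <- function(det, r_amp) tibble::tibble(qrs_detectability = det,
                                            mean_r_amp_mV = r_amp)
  expect_equal(classify_ecg(mk(1, 10), 0.01), "I")
  expect_equal(classify_ecg(mk(0.3, 10), 0.01), "II")
  expect_equal(classify_ecg(mk(1, NA_real_), 0.01), "II")
  expect_equal(classify_ecg(mk(1, 0.02), 0.01), "II")
})

test_that("poincare pairs, SD1/SD2 and errors behave", {
  const <- pp_intervals(tibble::tibble(p_time_s = cumsum(c(0, rep(0.52, 6)))))
  pc <- poincare_pairs(const)
  expect_true(all(pc$ibi_prev_s == 0.52 & pc$ibi_s == 0.52))
  expect_equal(attr(pc, "sd1"), 0)
  expect_equal(attr(pc, "sd2"), 0)
  iv <- pp_intervals(tibble::tibble(p_time_s = cumsum(c(0, stats::runif(20, 0.4, 0.7)))))
  expect_equal(nrow(poincare_pairs(iv)), nrow(iv) - 1)
  one <- pp_intervals(tibble::tibble(p_time_s = c(0, 0.5)))
  expect_error(poincare_pairs(one), class = "zfecg_insufficient")
})

test_that("mutant Poincare clouds contain long-pause ordinates; WT does not", {
  wt <- generate_beat_schedule(wt_config(duration_s = 60, seed = 1))
  # a seed whose Poisson draw realizes at least one pause (about 30% of
  # Class II recordings have none in a single minute at 1.2 episodes/min)
  mut <- generate_beat_schedule(class_ii_config(duration_s = 60, seed = 4))
  pc_wt <- poincare_pairs(truth_intervals(wt))
  pc_mut <- poincare_pairs(truth_intervals(mut))
  expect_true(all(pc_wt$ibi_s < 1.3))
  expect_true(any(pc_mut$ibi_s > 1.3))
  expect_lt(attr(pc_wt, "sd1"), attr(pc_mut, "sd1"))
})

test_that("rhythm parameters are recovered across replicate recordings", {
  recover <- function(mean_pp, sd_pp) {
    est <- vapply(1:50, function(s) {
      cfg <- sim_config(duration_s = 30, mean_pp_s = mean_pp, sd_pp_s = sd_pp,
                        seed = s)
      beats <- suppressWarnings(detect_beats(simulate_ecg(cfg)$trace))
      idx <- compute_indices(beats)
      c(idx$mean_pp_s, idx$sd_pp_s)
    }, numeric(2))
    mom <- zfecg:::truncnorm_lower_moments(mean_pp, sd_pp, 0.5 * mean_pp)
    se_mean <- stats::sd(est[1, ]) / sqrt(ncol(est))
    se_sd <- stats::sd(est[2, ]) / sqrt(ncol(est))
    expect_lt(abs(mean(est[1, ]) - mom$mean), 3 * se_mean)
    expect_lt(abs(mean(est[2, ]) - mom$sd), 3 * se_sd)
  }
  recover(0.52, 0.074)
  recover(0.54, 0.135)
})

test_that("the analytic truncated-normal moments match empirical draws", {
  set.seed(123)
  x <- zfecg:::rtruncnorm_lower(1e6, 0.54, 0.135, 0.27)
  mom <- zfecg:::truncnorm_lower_moments(0.54, 0.135, 0.27)
  expect_equal(mean(x), mom$mean, tolerance = 1e-3)
  expect_equal(stats::sd(x), mom$sd, tolerance = 1e-2)
})
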