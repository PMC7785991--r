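#' Per-recording ECG indices
#'
#' Computes the standard single-recording indices: heart rate (defined as
#' 60 over the mean P-P interval, so `hr_bpm * mean_pp_s == 60` exactly),
#' interval mean and sample SD (n-1 denominator), mean P and R amplitudes,
#' the P-amplitude to R-amplitude ratio, mean PR interval (P peak to QRS
#' onset), mean QRS duration, and the fraction of beats with a detected
#' QRS. QRS-dependent fields are `NA` (absent, not zero) when no beat
#' carries a QRS, mirroring the convention of reporting R-wave parameters
#' only for recordings with a distinguishable QRS.
#'
#' @param beats A `beat_set`.
#' @param intervals An `interval_series`; computed from `beats` when
#'   omitted.
#' @return An `ecg_indices` tibble with one row: `n_beats`, `hr_bpm`,
#'   `mean_pp_s`, `sd_pp_s`, `mean_p_amp_mV`, `mean_r_amp_mV`,
#'   `p_over_r_ratio`, `mean_pr_s`, `mean_qrs_s`, `qrs_detectability`.
#' @examples
#' rec <- simulate_ecg(wt_config(duration_s = 8, seed = 5))
#' compute_indices(detect_beats(rec$trace))
#' @export
compute_indices <- function(beats, intervals = pp_intervals(beats)) {
  if (nrow(intervals) < 1) {
    abort_zfecg("Interval series is empty.", "zfecg_insufficient")
  }
  pp <- intervals$pp_s
  mean_pp <- mean(pp)

  qrs <- beats[beats$qrs_detected, , drop = FALSE]
  has_qrs <- nrow(qrs) > 0
  mean_r <- if (has_qrs) mean(qrs$r_amp_mV, na.rm = TRUE) else NA_real_
  mean_p <- mean(beats$p_amp_mV, na.rm = TRUE)
  mean_pr <- if (has_qrs) mean(qrs$qrs_onset_s - qrs$p_time_s, na.rm = TRUE) else NA_real_
  qrs_dur <- qrs$qrs_offset_s - qrs$qrs_onset_s
  mean_qrs <- if (has_qrs && any(!is.na(qrs_dur))) mean(qrs_dur, na.rm = TRUE) else NA_real_

  out <- tibble::tibble(
    n_beats = nrow(beats),
    hr_bpm = 60 / mean_pp,
    mean_pp_s = mean_pp,
    sd_pp_s = stats::sd(pp),
    mean_p_amp_mV = mean_p,
    mean_r_amp_mV = mean_r,
    p_over_r_ratio = if (has_qrs) mean_p / mean_r else NA_real_,
    mean_pr_s = mean_pr,
    mean_qrs_s = mean_qrs,
    qrs_detectability = mean(beats$qrs_detected)
  )
  class(out) <- c("ecg_indices", class(out))
  out
}

#' @export
tidy.ecg_indices <- function(x, ...) {
  tibble::tibble(metric = names(x), value = as.numeric(x[1, ]))
}

#' @export
glance.ecg_indices <- function(x, ...) tibble::as_tibble(unclass(x))

#' Estimate the noise floor of a recording
#'
#' Median absolute deviation of the band-passed (QRS band) signal outside
#' detected beats: samples within 150 ms of any P or R fiducial are
#' masked. Band-passing first removes baseline wander so the estimate
#' reflects measurement noise rather than slow drift.
#'
#' @param trace An `ecg_trace`.
#' @param beats A `beat_set` detected on that trace.
#' @param params A [detector_params()].
#' @return Noise floor in millivolts (scalar).
#' @export
estimate_noise_floor <- function(trace, beats, params = detector_params()) {
  v <- trace$voltage_mV
  fs <- ecg_fs(trace)
  bp <- bandpass(v, fs, params$bp_low, params$bp_high)
  mask <- rep(FALSE, length(v))
  half <- round(0.15 * fs)
  marks <- c(beats$p_time_s, beats$r_time_s[!is.na(beats$r_time_s)])
  for (tm in marks) {
    i <- round(tm * fs) + 1L
    lo <- max(1L, i - half)
    hi <- min(length(v), i + half)
    mask[lo:hi] <- TRUE
  }
  keep <- bp[!mask]
  if (length(keep) < fs / 2) keep <- bp
  stats::mad(keep)
}

#' Classify a recording by QRS distinguishability
#'
#' Implements the two-class phenotype split: a recording is Class II
#' (indistinguishable QRS) when fewer than half of its beats have a
#' detected QRS, or when the mean R amplitude fails to clear three times
#' the recording's noise floor; otherwise it is Class I.
#'
#' @param indices An `ecg_indices` row from [compute_indices()].
#' @param noise_floor_mV Noise floor from [estimate_noise_floor()].
#' @return `"I"` or `"II"`.
#' @examples
#' rec <- simulate_ecg(wt_config(duration_s = 8, seed = 5))
#' b <- detect_beats(rec$trace)
#' classify_ecg(compute_indices(b), estimate_noise_floor(rec$trace, b))
#' @export
classify_ecg <- function(indices, noise_floor_mV) {
  if (indices$qrs_detectability < 0.5) return("II")
  if (is.na(indices$mean_r_amp_mV)) return("II")
  if (indices$mean_r_amp_mV < 3 * noise_floor_mV) return("II")
  "I"
}
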