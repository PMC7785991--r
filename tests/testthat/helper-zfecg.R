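# shared fixtures and oracles for the test suite

# preset with noise and wander switched off (deterministic morphology)
noiseless <- function(cfg_fn = wt_config, duration_s = 20, seed = 1L, ...) {
  cfg_fn(duration_s = duration_s, seed = seed,
         noise_sd_mV = 0, wander_amp_mV = 0, ...)
}

# build a beat schedule by hand (bypasses the interval sampler) so that
# rendering tests control beat placement exactly
manual_schedule <- function(p_times_s, config) {
  structure(
    list(p_times_s = p_times_s, injected_pause_indices = integer(0),
         class_label = if (config$qrs_suppression < 0.5) "II" else "I",
         config = config),
    class = "beat_schedule"
  )
}

# deliberately naive, independent R-peak detector used as a cross-check:
# detrend with a rolling median, threshold at half the global maximum, one
# detection per suprathreshold run, minimum gap enforced
naive_r_detector <- function(trace, min_gap_s = 0.2) {
  fs <- attr(trace, "fs")
  v <- trace$voltage_mV
  v <- v - stats::runmed(v, zfecg:::odd_window(0.5 * fs))
  thr <- 0.5 * max(v)
  runs <- rle(v > thr)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- mapply(function(s, e) s - 1L + which.max(v[s:e]),
                starts[runs$values], ends[runs$values])
  t <- (idx - 1) / fs
  t[c(TRUE, diff(t) > min_gap_s)]
}

# fraction of reference times matched by a detection within tol
match_frac <- function(ref_t, det_t, tol = 0.01) {
  if (length(ref_t) == 0) return(NA_real_)
  if (length(det_t) == 0) return(0)
  mean(vapply(ref_t, function(t) any(abs(det_t - t) <= tol), logical(1)))
}

# truth R-peak times implied by a beat schedule
truth_r_times <- function(truth) {
  cfg <- truth$config
  truth$p_times_s + cfg$pr_interval_s + cfg$qrs_duration_s / 2
}

# interval series straight from ground truth
truth_intervals <- function(truth) {
  pp_intervals(tibble::tibble(p_time_s = truth$p_times_s))
}

# hand-computed pooled-variance two-sample t-test (independent oracle)
t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
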