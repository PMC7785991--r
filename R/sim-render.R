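# Gaussian-bump waveform synthesis.
#
# Shape constants tie the rendered morphology to the interval indices the
# analysis reports:
#   * the R bump SD is chosen so that |voltage| falls to 10% of the R peak
#     at +/- qrs_duration/2 (the same 10%-of-peak rule the QRS delineator
#     uses), making the nominal QRS duration recoverable by measurement;
#   * the P bump full width at half maximum is qrs_duration/2;
#   * small negative Q and S bumps (12% of R, half the R width) flank R at
#     +/- 0.28 * qrs_duration;
#   * a broad low T bump follows the QRS.

add_gauss <- function(v, fs, center, amp, sd) {
  if (amp == 0) return(v)
  i0 <- max(1L, floor((center - 4 * sd) * fs) + 1L)
  i1 <- min(length(v), ceiling((center + 4 * sd) * fs) + 1L)
  if (i0 > i1) return(v)
  tt <- (seq.int(i0, i1) - 1) / fs
  v[i0:i1] <- v[i0:i1] + amp * exp(-0.5 * ((tt - center) / sd)^2)
  v
}

#' Render a beat schedule into a sampled voltage trace
#'
#' Each beat is synthesized as a sum of Gaussian bumps: a P bump at the
#' scheduled P time, a Q/R/S triplet whose R center sits at
#' `p_time + pr_interval + qrs_duration / 2` with R amplitude
#' `r_amp_mV * qrs_suppression`, and a broad T bump after the QRS. White
#' measurement noise and sinusoidal baseline wander are added on top, and
#' the result is sampled at `fs`.
#'
#' @param truth A `beat_schedule` from [generate_beat_schedule()].
#' @return An `ecg_trace`: a tibble with columns `time_s` and `voltage_mV`
#'   and attributes `fs`, `subject_id`, `group` and `config`.
#' @examples
#' tr <- render_trace(generate_beat_schedule(sim_config(duration_s = 5, seed = 1)))
#' nrow(tr)
#' @export
render_trace <- function(truth) {
  if (!inherits(truth, "beat_schedule")) {
    abort_zfecg("`truth` must be a beat_schedule.", "zfecg_input")
  }
  cfg <- truth$config
  p <- truth$p_times_s
  if (length(p) < 1) abort_zfecg("Beat schedule is empty.", "zfecg_input")
  if (length(p) > 1 && any(diff(p) < cfg$pr_interval_s + cfg$qrs_duration_s)) {
    abort_zfecg(
      "Overlapping beats: an interval is shorter than pr_interval_s + qrs_duration_s.",
      "zfecg_overlap"
    )
  }

  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  v <- numeric(n)

  sd_p <- (cfg$qrs_duration_s / 2) / (2 * sqrt(2 * log(2)))
  sd_r <- cfg$qrs_duration_s / (2 * sqrt(2 * log(10)))
  sd_qs <- sd_r / 2
  sd_t <- 0.03
  # the negative Q and S bumps leak slightly into the R center; scale the
  # R bump up by the analytic leak so the composite peak equals the
  # configured R amplitude exactly
  qs_leak <- exp(-0.5 * (0.28 * cfg$qrs_duration_s / sd_qs)^2)
  r_amp <- cfg$r_amp_mV * cfg$qrs_suppression / (1 - 2 * 0.12 * qs_leak)
  qs_amp <- 0.12 * r_amp

  for (pc in p) {
    rc <- pc + cfg$pr_interval_s + cfg$qrs_duration_s / 2
    v <- add_gauss(v, fs, pc, cfg$p_amp_mV, sd_p)
    v <- add_gauss(v, fs, rc - 0.28 * cfg$qrs_duration_s, -qs_amp, sd_qs)
    v <- add_gauss(v, fs, rc, r_amp, sd_r)
    v <- add_gauss(v, fs, rc + 0.28 * cfg$qrs_duration_s, -qs_amp, sd_qs)
    v <- add_gauss(v, fs, rc + 0.5 * cfg$qrs_duration_s + 0.08, cfg$t_amp_mV, sd_t)
  }

  tt <- (seq_len(n) - 1) / fs
  render_seed <- (cfg$seed + 500009L) %% 2147483647L
  withr::with_seed(render_seed, {
    if (cfg$noise_sd_mV > 0) v <- v + stats::rnorm(n, 0, cfg$noise_sd_mV)
    if (cfg$wander_amp_mV > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      v <- v + cfg$wander_amp_mV * sin(2 * pi * cfg$wander_freq_hz * tt + phase)
    }
  })

  new_ecg_trace(tt, v, fs, config = cfg)
}

#' Simulate one annotated recording
#'
#' Convenience wrapper chaining [generate_beat_schedule()] and
#' [render_trace()].
#'
#' @param config A [sim_config()].
#' @return A list with elements `trace` (the `ecg_trace`) and `truth` (the
#'   `beat_schedule` that generated it).
#' @examples
#' rec <- simulate_ecg(sim_config(duration_s = 5, seed = 4))
#' rec$truth$class_label
#' @export
simulate_ecg <- function(config) {
  truth <- generate_beat_schedule(config)
  list(trace = render_trace(truth), truth = truth)
}
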