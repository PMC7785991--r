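#' Parameterize a synthetic zebrafish ECG recording
#'
#' A `sim_config` fully describes one simulated recording: the rhythm model
#' (truncated-normal interbeat intervals with Poisson-injected sinus
#' pauses), the waveform morphology (Gaussian P, Q/R/S and T bumps), the
#' measurement noise model, and the seed that makes the simulation
#' reproducible.
#'
#' Defaults describe a healthy adult wildtype fish at ambient temperature:
#' a ~115 bpm sinus rhythm (mean P-P 0.52 s, SD 0.074 s), a 0.045 mV P
#' wave, a 0.248 mV R wave, a 33 ms PR interval and a ~51 ms QRS complex,
#' recorded for one minute at 1 kHz with 5 uV white noise and slow
#' baseline wander.
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz (at least 100).
#' @param mean_pp_s,sd_pp_s Mean and standard deviation of the baseline
#'   interbeat (P-P) interval in seconds. Intervals are drawn from a normal
#'   truncated below at `0.5 * mean_pp_s`.
#' @param sa_rate_per_min Expected number of injected sinus-arrest pauses
#'   per minute (Poisson).
#' @param sa_pause_min_s,sa_pause_max_s Uniform range of injected pause
#'   durations in seconds; the lower bound must exceed `mean_pp_s`.
#' @param p_consecutive Probability that an injected pause is immediately
#'   followed by another (geometric run extension), modelling consecutive
#'   sinus-arrest episodes.
#' @param p_amp_mV,r_amp_mV,t_amp_mV Peak amplitudes of the P, R and T
#'   bumps in millivolts.
#' @param pr_interval_s PR interval in seconds, measured P peak to QRS
#'   onset.
#' @param qrs_duration_s QRS duration in seconds (total support of the
#'   Q/R/S triplet).
#' @param qrs_suppression Multiplicative factor in `[0, 1]` applied to the
#'   Q/R/S amplitudes. Values much below 1 emulate the mutant phenotype in
#'   which the QRS complex is indistinguishable from noise.
#' @param noise_sd_mV Standard deviation of additive white measurement
#'   noise in millivolts.
#' @param wander_amp_mV,wander_freq_hz Amplitude and frequency of the
#'   sinusoidal baseline wander.
#' @param seed Integer seed controlling all randomness for this recording.
#' @return A `sim_config` object (a validated named list).
#' @seealso [wt_config()], [class_i_config()], [class_ii_config()],
#'   [generate_beat_schedule()], [render_trace()]
#' @examples
#' cfg <- sim_config(duration_s = 10, seed = 7)
#' cfg$mean_pp_s
#' @export
sim_config <- function(duration_s = 60, fs = 1000,
                       mean_pp_s = 0.52, sd_pp_s = 0.074,
                       sa_rate_per_min = 0,
                       sa_pause_min_s = 1.43, sa_pause_max_s = 3.0,
                       p_consecutive = 0,
                       p_amp_mV = 0.045, r_amp_mV = 0.248, t_amp_mV = 0.01,
                       pr_interval_s = 0.033, qrs_duration_s = 0.0512,
                       qrs_suppression = 1,
                       noise_sd_mV = 0.005,
                       wander_amp_mV = 0.02, wander_freq_hz = 0.3,
                       seed = 1L) {
  cfg <- list(
    duration_s = duration_s, fs = fs,
    mean_pp_s = mean_pp_s, sd_pp_s = sd_pp_s,
    sa_rate_per_min = sa_rate_per_min,
    sa_pause_min_s = sa_pause_min_s, sa_pause_max_s = sa_pause_max_s,
    p_consecutive = p_consecutive,
    p_amp_mV = p_amp_mV, r_amp_mV = r_amp_mV, t_amp_mV = t_amp_mV,
    pr_interval_s = pr_interval_s, qrs_duration_s = qrs_duration_s,
    qrs_suppression = qrs_suppression,
    noise_sd_mV = noise_sd_mV,
    wander_amp_mV = wander_amp_mV, wander_freq_hz = wander_freq_hz,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) abort_zfecg(msg, "zfecg_config")
  if (!is.numeric(cfg$duration_s) || cfg$duration_s <= 0) bad("`duration_s` must be > 0.")
  if (cfg$fs < 100) bad("`fs` must be at least 100 Hz.")
  if (!(cfg$sd_pp_s > 0 && cfg$sd_pp_s < cfg$mean_pp_s)) {
    bad("`sd_pp_s` must satisfy 0 < sd_pp_s < mean_pp_s.")
  }
  if (cfg$sa_rate_per_min < 0) bad("`sa_rate_per_min` must be >= 0.")
  if (cfg$sa_pause_min_s <= cfg$mean_pp_s) bad("`sa_pause_min_s` must exceed `mean_pp_s`.")
  if (cfg$sa_pause_max_s < cfg$sa_pause_min_s) bad("`sa_pause_max_s` must be >= `sa_pause_min_s`.")
  if (cfg$p_consecutive < 0 || cfg$p_consecutive >= 1) bad("`p_consecutive` must lie in [0, 1).")
  if (cfg$qrs_suppression < 0 || cfg$qrs_suppression > 1) bad("`qrs_suppression` must lie in [0, 1].")
  amps <- c(cfg$p_amp_mV, cfg$r_amp_mV, cfg$t_amp_mV, cfg$noise_sd_mV, cfg$wander_amp_mV)
  if (any(amps < 0)) bad("Amplitudes and noise levels must be >= 0.")
  if (cfg$pr_interval_s <= 0 || cfg$qrs_duration_s <= 0) bad("PR interval and QRS duration must be > 0.")
  if (!is.integer(cfg$seed) || is.na(cfg$seed)) bad("`seed` must be an integer.")
  invisible(cfg)
}

#' Preset simulation conditions for the study groups
#'
#' Three presets describe the cohort conditions the simulator emulates.
#'
#' `wt_config()` is a healthy wildtype fish: regular ~115 bpm rhythm
#' (mean P-P 0.52 s, SD 0.074 s), no sinus pauses, tall 0.248 mV R wave.
#'
#' `class_i_config()` is a mutant with a distinguishable but weakened QRS:
#' slightly slower and more variable rhythm (mean 0.539 s, SD 0.103 s),
#' occasional pauses (0.5 episodes/min), a 5-fold smaller R wave
#' (0.063 mV), prolonged PR (0.050 s) and QRS (0.0721 s).
#'
#' `class_ii_config()` is a severe mutant whose QRS is indistinguishable
#' from noise: highly variable rhythm (mean 0.54 s, SD 0.148 s), frequent
#' pauses (1.2 injected episodes/min with a 0.25 chance of immediate
#' extension, so about 1.6 pause intervals per minute overall), QRS
#' amplitudes suppressed to 10% and measurement noise doubled.
#'
#' @param seed Integer seed for the recording.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config` object.
#' @examples
#' class_ii_config(seed = 3)$qrs_suppression
#' @export
wt_config <- function(seed = 1L, ...) {
  do.call(sim_config, modifyList(list(seed = seed), list(...)))
}

#' @rdname wt_config
#' @export
class_i_config <- function(seed = 1L, ...) {
  base <- list(
    mean_pp_s = 0.539, sd_pp_s = 0.103,
    sa_rate_per_min = 0.5, p_consecutive = 0.1,
    p_amp_mV = 0.055, r_amp_mV = 0.063,
    pr_interval_s = 0.050, qrs_duration_s = 0.0721,
    seed = seed
  )
  do.call(sim_config, modifyList(base, list(...)))
}

#' @rdname wt_config
#' @export
class_ii_config <- function(seed = 1L, ...) {
  base <- list(
    mean_pp_s = 0.54, sd_pp_s = 0.148,
    sa_rate_per_min = 1.2, p_consecutive = 0.25,
    p_amp_mV = 0.055, r_amp_mV = 0.248, qrs_suppression = 0.1,
    pr_interval_s = 0.050, qrs_duration_s = 0.0721,
    noise_sd_mV = 0.010,
    seed = seed
  )
  do.call(sim_config, modifyList(base, list(...)))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  rhythm: mean P-P %.3f s (SD %.3f s), %g s at %g Hz\n",
              x$mean_pp_s, x$sd_pp_s, x$duration_s, x$fs))
  cat(sprintf("  pauses: %.2f/min on [%.2f, %.2f] s, P(run extends) = %.2f\n",
              x$sa_rate_per_min, x$sa_pause_min_s, x$sa_pause_max_s, x$p_consecutive))
  cat(sprintf("  waves:  P %.3f mV, R %.3f mV (x%.2f), PR %.3f s, QRS %.4f s\n",
              x$p_amp_mV, x$r_amp_mV, x$qrs_suppression,
              x$pr_interval_s, x$qrs_duration_s))
  cat(sprintf("  noise:  %.4f mV white, wander %.3f mV @ %.2f Hz, seed %d\n",
              x$noise_sd_mV, x$wander_amp_mV, x$wander_freq_hz, x$seed))
  invisible(x)
}
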