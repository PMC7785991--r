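#' Generate the ground-truth beat schedule for one recording
#'
#' Draws baseline interbeat intervals from a normal distribution truncated
#' below at half the mean (preventing nonphysically short intervals).
#' Sinus-arrest episodes arrive as a Poisson process in recording time
#' (rate `sa_rate_per_min`); each onset replaces the interval starting at
#' the first beat at or after it with a long pause drawn uniformly from
#' `[sa_pause_min_s, sa_pause_max_s]`. After each injected pause the next
#' interval is also replaced with probability `p_consecutive`, producing
#' runs of consecutive pauses. The schedule is truncated at `duration_s`.
#'
#' @param config A [sim_config()].
#' @return A `beat_schedule` object: a list with `p_times_s` (strictly
#'   increasing P-peak times), `injected_pause_indices` (1-based indices
#'   into `diff(p_times_s)` that were replaced by pauses), `class_label`
#'   (`"I"` when the QRS is rendered at full amplitude, `"II"` when it is
#'   strongly suppressed) and the `config`.
#' @examples
#' sched <- generate_beat_schedule(sim_config(duration_s = 10, seed = 2))
#' length(sched$p_times_s)
#' @export
generate_beat_schedule <- function(config) {
  validate_sim_config(config)
  mean_pause <- (config$sa_pause_min_s + config$sa_pause_max_s) / 2
  expected_pause_time <- config$sa_rate_per_min * config$duration_s / 60 * mean_pause
  if (expected_pause_time > config$duration_s) {
    abort_zfecg(
      "Expected total pause time exceeds the recording duration; lower `sa_rate_per_min`.",
      "zfecg_config"
    )
  }

  withr::with_seed(config$seed, {
    t0 <- 0.1
    lower <- 0.5 * config$mean_pp_s

    # sinus-arrest episodes are a Poisson process in recording time: each
    # onset turns the interval beginning at the first beat at or after it
    # into a pause, so the realized episode rate tracks sa_rate_per_min
    # regardless of how much time the pauses themselves consume
    n_ep <- stats::rpois(1, config$sa_rate_per_min * config$duration_s / 60)
    onsets <- sort(stats::runif(n_ep, 0, config$duration_s))

    iv <- numeric(0)
    injected <- integer(0)
    t <- t0
    k <- 1L
    extend <- FALSE
    while (t < config$duration_s) {
      if (extend || (k <= n_ep && onsets[k] <= t)) {
        iv <- c(iv, stats::runif(1, config$sa_pause_min_s, config$sa_pause_max_s))
        injected <- c(injected, length(iv))
        if (!extend) k <- k + 1L
        extend <- stats::runif(1) < config$p_consecutive
      } else {
        iv <- c(iv, rtruncnorm_lower(1, config$mean_pp_s, config$sd_pp_s, lower))
        extend <- FALSE
      }
      t <- t + iv[length(iv)]
    }

    p <- t0 + cumsum(c(0, iv))
    # leave room for the last beat's QRS and T wave inside the trace
    margin <- config$pr_interval_s + config$qrs_duration_s + 0.15
    keep <- p <= config$duration_s - margin
    p <- p[keep]
    injected <- injected[injected <= length(p) - 1L]

    structure(
      list(
        p_times_s = p,
        injected_pause_indices = injected,
        class_label = if (config$qrs_suppression < 0.5) "II" else "I",
        config = config
      ),
      class = "beat_schedule"
    )
  })
}

#' @export
print.beat_schedule <- function(x, ...) {
  cat(sprintf("<beat_schedule> %d beats over %.1f s, %d injected pause(s), class %s\n",
              length(x$p_times_s),
              diff(range(x$p_times_s)),
              length(x$injected_pause_indices),
              x$class_label))
  invisible(x)
}
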