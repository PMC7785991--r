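#' Derive the sinus-arrest interval cutoff from the normal rhythm
#'
#' The definitive sinus-arrest cutoff is a fold change over the normal
#' mean interbeat interval: with a wildtype mean of 0.52 s and the default
#' 2.5-fold increase, the cutoff is 1.3 s.
#'
#' @param wt_mean_pp_s Normal (wildtype) mean P-P interval in seconds.
#' @param fold Fold increase defining an abnormal pause (> 1).
#' @return Cutoff in seconds.
#' @examples
#' derive_sa_cutoff(0.52)
#' @export
derive_sa_cutoff <- function(wt_mean_pp_s, fold = 2.5) {
  if (wt_mean_pp_s <= 0) abort_zfecg("`wt_mean_pp_s` must be positive.", "zfecg_domain")
  if (fold < 1) abort_zfecg("`fold` must be >= 1.", "zfecg_domain")
  fold * wt_mean_pp_s
}

#' Score sinus-arrest episodes in an interval series
#'
#' Every interval exceeding the definitive cutoff (default 1.3 s) counts
#' as exactly one sinus-arrest episode, regardless of its length.
#' Intervals exceeding the milder screening cutoff (default 1.0 s) are
#' reported alongside but do not enter the episode counts. Consecutive
#' incidence is counted as maximal runs of at least two adjacent episode
#' intervals (`consecutive_unit = "runs"`, one run = one incidence) or,
#' alternatively, as the number of episode intervals belonging to such
#' runs (`"episodes"`). Per-minute frequencies divide by the recording
#' duration carried by the interval series.
#'
#' @param intervals An `interval_series` from [pp_intervals()].
#' @param definitive_cutoff_s Definitive episode cutoff in seconds.
#' @param screening_cutoff_s Screening cutoff in seconds (must not exceed
#'   the definitive cutoff).
#' @param consecutive_unit How consecutive incidence is counted; see
#'   above.
#' @return An `sa_report` list: cutoffs, `episode_indices`,
#'   `screened_indices`, `n_episodes`, `episodes_per_min`,
#'   `n_consecutive_runs`, `consecutive_runs_per_min`, `has_sa`,
#'   `recording_duration_min`, `n_intervals` and the interval values
#'   (`pp_s`).
#' @examples
#' iv <- pp_intervals(tibble::tibble(p_time_s = cumsum(c(0, 0.5, 0.5, 1.4, 0.5))))
#' detect_sa_episodes(iv)$n_episodes
#' @export
detect_sa_episodes <- function(intervals, definitive_cutoff_s = 1.3,
                               screening_cutoff_s = 1.0,
                               consecutive_unit = c("runs", "episodes")) {
  consecutive_unit <- match.arg(consecutive_unit)
  if (nrow(intervals) < 1) abort_zfecg("Interval series is empty.", "zfecg_insufficient")
  if (definitive_cutoff_s < screening_cutoff_s) {
    abort_zfecg("Definitive cutoff must be >= screening cutoff.", "zfecg_input")
  }
  dur_min <- interval_duration_min(intervals)
  if (!is.finite(dur_min) || dur_min <= 0) {
    abort_zfecg("Recording duration must be positive.", "zfecg_input")
  }

  pp <- intervals$pp_s
  episodes <- which(pp > definitive_cutoff_s)
  screened <- which(pp > screening_cutoff_s)

  is_ep <- pp > definitive_cutoff_s
  r <- rle(is_ep)
  run_lengths <- r$lengths[r$values]
  n_runs <- sum(run_lengths >= 2)
  n_consec <- switch(consecutive_unit,
    runs = n_runs,
    episodes = sum(run_lengths[run_lengths >= 2])
  )

  structure(
    list(
      definitive_cutoff_s = definitive_cutoff_s,
      screening_cutoff_s = screening_cutoff_s,
      episode_indices = episodes,
      screened_indices = screened,
      n_episodes = length(episodes),
      episodes_per_min = length(episodes) / dur_min,
      n_consecutive_runs = n_consec,
      consecutive_runs_per_min = n_consec / dur_min,
      consecutive_unit = consecutive_unit,
      has_sa = length(episodes) >= 1,
      recording_duration_min = dur_min,
      n_intervals = length(pp),
      pp_s = pp
    ),
    class = "sa_report"
  )
}

#' @export
print.sa_report <- function(x, ...) {
  cat(sprintf(
    "<sa_report> %d episode(s) > %.2f s in %.2f min (%.2f/min), %d consecutive %s\n",
    x$n_episodes, x$definitive_cutoff_s, x$recording_duration_min,
    x$episodes_per_min, x$n_consecutive_runs, x$consecutive_unit
  ))
  invisible(x)
}

#' @export
tidy.sa_report <- function(x, ...) {
  tibble::tibble(
    interval_idx = x$screened_indices,
    pp_s = x$pp_s[x$screened_indices],
    definitive = x$screened_indices %in% x$episode_indices
  )
}

#' @export
glance.sa_report <- function(x, ...) {
  tibble::tibble(
    n_intervals = x$n_intervals,
    n_episodes = x$n_episodes,
    episodes_per_min = x$episodes_per_min,
    n_consecutive_runs = x$n_consecutive_runs,
    consecutive_runs_per_min = x$consecutive_runs_per_min,
    has_sa = x$has_sa,
    recording_duration_min = x$recording_duration_min
  )
}

#' Cohort prevalence and frequency of sinus arrest
#'
#' Summarises per-recording sinus-arrest reports by group: how many fish
#' show at least one episode, the percentage that do, and the per-fish
#' mean episode and consecutive-run frequencies (each fish's per-minute
#' rate is computed first and the rates are then averaged, so fish with
#' short recordings are not over-weighted).
#'
#' @param reports A tibble with one row per recording and columns `group`,
#'   `has_sa`, `episodes_per_min`, `consecutive_runs_per_min` and
#'   `n_beats`. [glance()] on an `sa_report` plus a group label supplies
#'   all but `n_beats`; `n_beats` is `n_intervals + 1`.
#' @return A tibble with one row per group: `group`, `n_fish`,
#'   `n_with_sa`, `percent_with_sa`, `mean_episodes_per_min`,
#'   `mean_consecutive_runs_per_min`, `total_beats`.
#' @examples
#' df <- tibble::tibble(group = "mut", has_sa = c(TRUE, FALSE),
#'                      episodes_per_min = c(1, 0),
#'                      consecutive_runs_per_min = 0, n_beats = c(100, 110))
#' cohort_prevalence(df)
#' @export
cohort_prevalence <- function(reports) {
  need <- c("group", "has_sa", "episodes_per_min", "consecutive_runs_per_min", "n_beats")
  if (!all(need %in% names(reports))) {
    abort_zfecg(sprintf("`reports` needs columns: %s.", paste(need, collapse = ", ")),
                "zfecg_input")
  }
  if (nrow(reports) == 0) abort_zfecg("`reports` is empty.", "zfecg_input")
  reports |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_fish = dplyr::n(),
      n_with_sa = sum(.data$has_sa),
      percent_with_sa = 100 * sum(.data$has_sa) / dplyr::n(),
      mean_episodes_per_min = mean(.data$episodes_per_min),
      mean_consecutive_runs_per_min = mean(.data$consecutive_runs_per_min),
      total_beats = sum(.data$n_beats),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group)
}
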