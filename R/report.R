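#' Analyze one recording end to end
#'
#' Runs beat detection, interval extraction, index computation,
#' classification and sinus-arrest scoring on a single trace and returns a
#' one-row tibble suitable for binding into a cohort table.
#'
#' @param trace An `ecg_trace`.
#' @param params A [detector_params()].
#' @param definitive_cutoff_s,screening_cutoff_s Sinus-arrest cutoffs
#'   passed to [detect_sa_episodes()].
#' @return A one-row tibble: `subject_id`, `group`, the [compute_indices()]
#'   columns, `ecg_class`, `noise_floor_mV`, and the [glance()] columns of
#'   the recording's `sa_report`.
#' @examples
#' rec <- simulate_ecg(wt_config(duration_s = 8, seed = 9))
#' analyze_recording(rec$trace)$ecg_class
#' @export
analyze_recording <- function(trace, params = detector_params(),
                              definitive_cutoff_s = 1.3,
                              screening_cutoff_s = 1.0) {
  beats <- detect_beats(trace, params)
  intervals <- pp_intervals(beats)
  idx <- compute_indices(beats, intervals)
  floor_ <- estimate_noise_floor(trace, beats, params)
  cls <- classify_ecg(idx, floor_)
  sa <- detect_sa_episodes(intervals, definitive_cutoff_s, screening_cutoff_s)
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = attr(trace, "subject_id") %||% NA_character_,
      group = attr(trace, "group") %||% NA_character_
    ),
    tibble::as_tibble(unclass(idx)),
    tibble::tibble(ecg_class = cls, noise_floor_mV = floor_),
    glance(sa)
  )
}

#' Analyze every recording of a simulated cohort
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param ... Passed on to [analyze_recording()].
#' @return A tibble with one row per recording.
#' @export
analyze_cohort <- function(cohort, ...) {
  rows <- purrr::map(cohort$trace, analyze_recording, ...)
  dplyr::bind_rows(rows)
}

report_metrics <- c(
  "hr_bpm", "mean_pp_s", "sd_pp_s", "mean_p_amp_mV", "mean_r_amp_mV",
  "p_over_r_ratio", "mean_pr_s", "mean_qrs_s"
)

#' Assemble a cohort report
#'
#' Builds the cohort-level tables from per-recording results: per-group
#' means and SDs of the ECG indices, pairwise pooled-variance t-tests of
#' each index against the reference group, sinus-arrest prevalence and
#' frequency per group, and the class breakdown. Assembly is a pure
#' function of its inputs with deterministic ordering, so re-running it on
#' the same results reproduces the report byte for byte.
#'
#' @param results Per-recording results from [analyze_cohort()] (or
#'   row-bound [analyze_recording()] outputs). May also be given as two
#'   tables via `sa_results`, in which case the tables are joined on
#'   `subject_id` and any mismatch aborts with the offending ids.
#' @param sa_results Optional separate sinus-arrest table with
#'   `subject_id` plus the [glance()] columns of each `sa_report`.
#' @param reference_group Group label the others are compared against.
#' @return A `cohort_report` list with elements `indices_summary`,
#'   `comparisons`, `sa_summary`, `class_counts` and `n_recordings`.
#' @export
build_cohort_report <- function(results, sa_results = NULL,
                                reference_group = "WT") {
  if (!is.null(sa_results)) {
    only_a <- setdiff(results$subject_id, sa_results$subject_id)
    only_b <- setdiff(sa_results$subject_id, results$subject_id)
    if (length(only_a) + length(only_b) > 0) {
      abort_zfecg(
        sprintf("Subject ids do not match across inputs: %s.",
                paste(c(only_a, only_b), collapse = ", ")),
        "zfecg_id_mismatch"
      )
    }
    results <- dplyr::left_join(results, sa_results, by = "subject_id")
  }
  results <- dplyr::arrange(results, .data$group, .data$subject_id)

  metrics <- intersect(report_metrics, names(results))
  indices_summary <- results |>
    tidyr::pivot_longer(dplyr::all_of(metrics),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$metric, .data$group)

  others <- setdiff(sort(unique(results$group)), reference_group)
  comparisons <- list()
  for (g in others) {
    for (m in metrics) {
      a <- results[[m]][results$group == reference_group]
      b <- results[[m]][results$group == g]
      a <- a[!is.na(a)]
      b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) next
      if (stats::var(a) + stats::var(b) == 0) next
      comparisons[[length(comparisons) + 1L]] <-
        unpaired_t_test(a, b, metric = m, group_a = reference_group, group_b = g)
    }
  }
  comparisons <- if (length(comparisons)) dplyr::bind_rows(comparisons) else NULL

  sa_summary <- cohort_prevalence(
    dplyr::select(results, "group", "has_sa", "episodes_per_min",
                  "consecutive_runs_per_min", "n_beats")
  )
  class_counts <- dplyr::count(results, .data$group, .data$ecg_class, name = "n") |>
    dplyr::arrange(.data$group, .data$ecg_class)

  structure(
    list(
      indices_summary = indices_summary,
      comparisons = comparisons,
      sa_summary = sa_summary,
      class_counts = class_counts,
      n_recordings = nrow(results),
      reference_group = reference_group
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d recordings, reference group %s\n",
              x$n_recordings, x$reference_group))
  cat("\nSinus-arrest summary:\n")
  print(x$sa_summary)
  cat("\nClass breakdown:\n")
  print(x$class_counts)
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits `report.json` (the full report at full precision) and CSVs for
#' the index summary, the group comparisons and the sinus-arrest summary.
#' Output is deterministic: identical reports produce identical files.
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    json = file.path(dir, "report.json"),
    indices = file.path(dir, "indices_summary.csv"),
    comparisons = file.path(dir, "comparisons.csv"),
    sa = file.path(dir, "sa_summary.csv")
  )
  jsonlite::write_json(
    list(
      n_recordings = report$n_recordings,
      reference_group = report$reference_group,
      indices_summary = report$indices_summary,
      comparisons = report$comparisons,
      sa_summary = report$sa_summary,
      class_counts = report$class_counts
    ),
    paths["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  readr::write_csv(report$indices_summary, paths["indices"], progress = FALSE)
  if (!is.null(report$comparisons)) {
    readr::write_csv(report$comparisons, paths["comparisons"], progress = FALSE)
  }
  readr::write_csv(report$sa_summary, paths["sa"], progress = FALSE)
  invisible(paths)
}
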