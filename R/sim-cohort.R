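#' Default three-group cohort manifest
#'
#' Mirrors the study cohort: 14 wildtype fish, 9 mutants with a
#' distinguishable QRS (Class I) and 5 mutants with an indistinguishable
#' QRS (Class II).
#'
#' @param duration_s Recording length passed to every preset.
#' @return A manifest tibble with columns `group`, `n` and `config`
#'   (a list-column of [sim_config()] objects).
#' @examples
#' default_cohort_manifest()
#' @export
default_cohort_manifest <- function(duration_s = 60) {
  tibble::tibble(
    group = c("WT", "ClassI", "ClassII"),
    n = c(14L, 9L, 5L),
    config = list(
      wt_config(duration_s = duration_s),
      class_i_config(duration_s = duration_s),
      class_ii_config(duration_s = duration_s)
    )
  )
}

subject_seed <- function(manifest_seed, index) {
  as.integer((as.numeric(manifest_seed) + 104729 * index) %% 2147483647)
}

#' Simulate an annotated cohort of recordings
#'
#' Generates `n` recordings per manifest row. Per-subject seeds are derived
#' deterministically from `seed` and the subject's position in the
#' manifest, so the same manifest and seed always reproduce the same cohort
#' (and, when `out_dir` is given, byte-identical files).
#'
#' @param manifest A tibble with columns `group` (unique labels), `n`
#'   (subjects per group, >= 1) and `config` (list-column of
#'   [sim_config()] objects).
#' @param seed Integer master seed for the cohort.
#' @param out_dir Optional directory; when given, each subject's trace is
#'   written as `<id>.csv` with a `<id>.json` metadata sidecar and a
#'   `<id>_truth.json` ground-truth file.
#' @return A tibble with one row per subject: `subject_id`, `group`, and
#'   list-columns `config`, `truth` and `trace`.
#' @examples
#' m <- tibble::tibble(group = "WT", n = 2L,
#'                     config = list(wt_config(duration_s = 5)))
#' simulate_cohort(m, seed = 1)
#' @export
simulate_cohort <- function(manifest, seed = 1L, out_dir = NULL) {
  need <- c("group", "n", "config")
  if (!all(need %in% names(manifest))) {
    abort_zfecg("`manifest` needs columns group, n and config.", "zfecg_input")
  }
  if (any(manifest$n < 1)) abort_zfecg("Each group needs n >= 1.", "zfecg_input")
  if (anyDuplicated(manifest$group)) {
    abort_zfecg("Duplicate group labels would produce duplicate subject ids.", "zfecg_input")
  }

  rows <- list()
  idx <- 0L
  for (g in seq_len(nrow(manifest))) {
    for (i in seq_len(manifest$n[g])) {
      idx <- idx + 1L
      cfg <- manifest$config[[g]]
      cfg$seed <- subject_seed(seed, idx)
      id <- sprintf("%s_%03d", manifest$group[g], i)
      rec <- simulate_ecg(cfg)
      attr(rec$trace, "subject_id") <- id
      attr(rec$trace, "group") <- manifest$group[g]
      rows[[idx]] <- tibble::tibble(
        subject_id = id, group = manifest$group[g],
        config = list(cfg), truth = list(rec$truth), trace = list(rec$trace)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$subject_id)) {
    abort_zfecg("Duplicate subject ids in cohort.", "zfecg_input")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_len(nrow(out))) {
      base <- file.path(out_dir, out$subject_id[r])
      write_trace(out$trace[[r]], paste0(base, ".csv"))
      write_truth(out$truth[[r]], paste0(base, "_truth.json"))
    }
  }
  out
}

#' Read and write ECG traces as CSV with a JSON metadata sidecar
#'
#' Traces travel as a two-column CSV (`time_s,voltage_mV`) plus a JSON
#' sidecar holding the subject id, group label, sampling rate and, for
#' simulated traces, an echo of the generating configuration.
#'
#' @param trace An `ecg_trace`.
#' @param path Path to the CSV file; the sidecar uses the same path with a
#'   `.json` extension.
#' @return `write_trace()` invisibly returns `path`; `read_trace()` returns
#'   an `ecg_trace`.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(tibble::tibble(time_s = trace$time_s,
                                  voltage_mV = trace$voltage_mV),
                   path, progress = FALSE)
  meta <- list(
    subject_id = attr(trace, "subject_id"),
    group = attr(trace, "group"),
    fs = ecg_fs(trace)
  )
  cfg <- attr(trace, "config")
  if (!is.null(cfg)) meta$config <- unclass(cfg)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- list(subject_id = NA_character_, group = NA_character_, fs = NULL)
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- modifyList(meta, jsonlite::read_json(sp, simplifyVector = TRUE))
  fs <- meta$fs %||% (1 / stats::median(diff(df$time_s)))
  cfg <- meta$config
  if (!is.null(cfg)) {
    cfg <- modifyList(cfg, list(seed = as.integer(cfg$seed)))
    class(cfg) <- "sim_config"
  }
  new_ecg_trace(df$time_s, df$voltage_mV, fs,
                subject_id = meta$subject_id %||% NA_character_,
                group = meta$group %||% NA_character_,
                config = cfg)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read and write ground-truth beat schedules as JSON
#'
#' @param truth A `beat_schedule`.
#' @param path Path to the JSON file.
#' @return `write_truth()` invisibly returns `path`; `read_truth()` returns
#'   a `beat_schedule`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(
      p_times_s = truth$p_times_s,
      injected_pause_indices = truth$injected_pause_indices,
      class_label = truth$class_label,
      config = unclass(truth$config)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- modifyList(x$config, list(seed = as.integer(x$config$seed)))
  class(cfg) <- "sim_config"
  structure(
    list(
      p_times_s = as.numeric(x$p_times_s),
      injected_pause_indices = as.integer(x$injected_pause_indices %||% integer(0)),
      class_label = x$class_label,
      config = cfg
    ),
    class = "beat_schedule"
  )
}
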