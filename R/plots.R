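#' Plot an ECG trace
#'
#' Voltage against time, with optional beat fiducials overlaid.
#'
#' @param object An `ecg_trace`.
#' @param beats Optional `beat_set`; P peaks (and R peaks when present)
#'   are marked.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_trace <- function(object, beats = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data$voltage_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Voltage (mV)") +
    ggplot2::theme_minimal()
  if (!is.null(beats)) {
    fid <- tibble::tibble(
      time_s = c(beats$p_time_s, beats$r_time_s),
      wave = rep(c("P", "R"), c(nrow(beats), nrow(beats)))
    )
    fid <- fid[!is.na(fid$time_s), , drop = FALSE]
    v <- object$voltage_mV
    fs <- ecg_fs(object)
    fid$voltage_mV <- v[pmin(length(v), round(fid$time_s * fs) + 1L)]
    p <- p + ggplot2::geom_point(
      data = fid,
      ggplot2::aes(colour = .data$wave), size = 1
    )
  }
  p
}

#' Poincare plot of consecutive interbeat intervals
#'
#' Each interval against its predecessor; a regular rhythm clusters on
#' the identity line. The dashed horizontal line marks the sinus-arrest
#' cutoff when supplied.
#'
#' @param object A `poincare_pairs` tibble.
#' @param cutoff_s Optional cutoff to mark (e.g. 1.3 s).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.poincare_pairs <- function(object, cutoff_s = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$ibi_prev_s, y = .data$ibi_s)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = expression(IBI[n - 1] ~ "(s)"), y = expression(IBI[n] ~ "(s)")) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff_s)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff_s, linetype = "dashed")
  }
  p
}

#' Plot an interval series with sinus-arrest cutoffs
#'
#' Interbeat intervals in beat order with the report's screening and
#' definitive cutoffs; flagged episodes are highlighted.
#'
#' @param object An `sa_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sa_report <- function(object, ...) {
  df <- tibble::tibble(
    interval_idx = seq_along(object$pp_s),
    pp_s = object$pp_s,
    episode = seq_along(object$pp_s) %in% object$episode_indices
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval_idx, y = .data$pp_s)) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$episode), size = 1) +
    ggplot2::geom_hline(yintercept = object$definitive_cutoff_s, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$screening_cutoff_s,
                        linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "Interval index", y = "P-P interval (s)", colour = "Episode") +
    ggplot2::theme_minimal()
}
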