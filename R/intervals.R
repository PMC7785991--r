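#' Interbeat (P-P) intervals from a beat table
#'
#' Successive differences of P-peak times. The recording duration carried
#' along for per-minute rates is the span from the first to the last P
#' peak, in minutes.
#'
#' @param beats A `beat_set` (or any tibble with a `p_time_s` column) with
#'   at least two beats.
#' @return An `interval_series`: a tibble with columns `interval_idx` and
#'   `pp_s`, with attribute `recording_duration_min`.
#' @examples
#' b <- tibble::tibble(p_time_s = c(0, 0.5, 1.0))
#' pp_intervals(b)$pp_s
#' @export
pp_intervals <- function(beats) {
  p <- beats$p_time_s
  if (length(p) < 2) {
    abort_zfecg("At least two beats are needed to form intervals.", "zfecg_insufficient")
  }
  if (any(diff(p) <= 0)) {
    abort_zfecg("P times must be strictly increasing.", "zfecg_input")
  }
  out <- tibble::tibble(interval_idx = seq_len(length(p) - 1L), pp_s = diff(p))
  attr(out, "recording_duration_min") <- (p[length(p)] - p[1]) / 60
  class(out) <- c("interval_series", class(out))
  out
}

interval_duration_min <- function(intervals) {
  dur <- attr(intervals, "recording_duration_min")
  if (is.null(dur)) dur <- sum(intervals$pp_s) / 60
  dur
}

#' Flag abnormally long interbeat intervals (mean + 2 SD rule)
#'
#' Flags intervals exceeding the within-recording mean plus two standard
#' deviations, the screening rule used to mark long pauses on ECG strips.
#'
#' @param intervals An `interval_series` with at least three intervals.
#' @return Integer vector of flagged interval indices (1-based).
#' @examples
#' iv <- pp_intervals(tibble::tibble(p_time_s = cumsum(c(0, rep(0.5, 19), 1.4))))
#' flag_long_beats(iv)
#' @export
flag_long_beats <- function(intervals) {
  pp <- intervals$pp_s
  if (length(pp) < 3) {
    abort_zfecg("At least three intervals are needed.", "zfecg_insufficient")
  }
  which(pp > mean(pp) + 2 * stats::sd(pp))
}

#' Poincare pairs of consecutive interbeat intervals
#'
#' Returns the lagged pairs (interval n-1, interval n) used for Poincare
#' plots, together with the SD1/SD2 ellipse descriptors: SD1 is the SD of
#' the pairwise differences divided by sqrt(2) (short-term variability,
#' spread across the identity line) and SD2 the SD of the pairwise sums
#' divided by sqrt(2) (long-term variability, spread along it).
#'
#' @param intervals An `interval_series` with at least two intervals.
#' @return A `poincare_pairs` tibble with columns `ibi_prev_s` and
#'   `ibi_s` (one row fewer than there are intervals) and attributes
#'   `sd1` and `sd2`.
#' @examples
#' iv <- pp_intervals(tibble::tibble(p_time_s = cumsum(c(0, rep(0.52, 5)))))
#' attr(poincare_pairs(iv), "sd1")
#' @export
poincare_pairs <- function(intervals) {
  pp <- intervals$pp_s
  m <- length(pp)
  if (m < 2) {
    abort_zfecg("At least two intervals are needed for Poincare pairs.", "zfecg_insufficient")
  }
  prev <- pp[-m]
  cur <- pp[-1]
  out <- tibble::tibble(ibi_prev_s = prev, ibi_s = cur)
  attr(out, "sd1") <- stats::sd((cur - prev) / sqrt(2))
  attr(out, "sd2") <- stats::sd((cur + prev) / sqrt(2))
  class(out) <- c("poincare_pairs", class(out))
  out
}

#' @export
glance.poincare_pairs <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x), sd1 = attr(x, "sd1"), sd2 = attr(x, "sd2"))
}
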