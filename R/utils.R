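# shared internal helpers

abort_zfecg <- function(msg, class) {
  rlang::abort(msg, class = c(class, "zfecg_error"))
}

# sampling rate of a trace; attribute when present, else inferred from time axis
ecg_fs <- function(trace) {
  fs <- attr(trace, "fs")
  if (is.null(fs)) fs <- 1 / stats::median(diff(trace$time_s))
  fs
}

new_ecg_trace <- function(time_s, voltage_mV, fs,
                          subject_id = NA_character_, group = NA_character_,
                          config = NULL) {
  out <- tibble::tibble(time_s = time_s, voltage_mV = voltage_mV)
  attr(out, "fs") <- fs
  attr(out, "subject_id") <- subject_id
  attr(out, "group") <- group
  if (!is.null(config)) attr(out, "config") <- config
  class(out) <- c("ecg_trace", class(out))
  out
}

# zero-phase Butterworth band-pass (order 2 applied forward and backward)
bandpass <- function(x, fs, lo, hi) {
  ny <- fs / 2
  bf <- signal::butter(2, c(lo, hi) / ny, type = "pass")
  signal::filtfilt(bf, x)
}

moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  y[is.na(y)] <- 0
  y
}

odd_window <- function(n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n + 1L else n
}

# lower-truncated normal draws by inverse CDF (upper tail unbounded)
rtruncnorm_lower <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

# analytic moments of the lower-truncated normal
truncnorm_lower_moments <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  z <- 1 - stats::pnorm(a)
  lam <- stats::dnorm(a) / z
  list(mean = mean + sd * lam,
       sd = sd * sqrt(1 + a * lam - lam^2))
}

#' Convert between heart rate and mean interbeat interval
#'
#' The heart rate in beats per minute and the mean P-P interval in seconds
#' are reciprocal by definition: `rate = 60 / interval`.
#'
#' @param bpm Heart rate in beats per minute.
#' @param pp_s Mean P-P interval in seconds.
#' @return A numeric vector (seconds for [bpm_to_pp()], bpm for
#'   [pp_to_bpm()]).
#' @examples
#' bpm_to_pp(115)
#' pp_to_bpm(0.52)
#' @export
bpm_to_pp <- function(bpm) {
  if (any(bpm <= 0)) abort_zfecg("`bpm` must be positive.", "zfecg_domain")
  60 / bpm
}

#' @rdname bpm_to_pp
#' @export
pp_to_bpm <- function(pp_s) {
  if (any(pp_s <= 0)) abort_zfecg("`pp_s` must be positive.", "zfecg_domain")
  60 / pp_s
}
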