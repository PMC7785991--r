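#' Detector settings
#'
#' All detector mechanics are governed by this settings object. Thresholds
#' are relative (multiples of rolling medians or median absolute
#' deviations), which makes every fiducial time invariant under rescaling
#' of the trace.
#'
#' @param bp_low,bp_high QRS band-pass corners in Hz.
#' @param k_r Threshold multiplier on the rolling median of the QRS energy
#'   envelope.
#' @param env_smooth_s Moving-average window applied to the squared
#'   derivative, in seconds.
#' @param env_floor_frac Floor on the envelope threshold, as a fraction of
#'   the envelope's 95th percentile (keeps low-amplitude ripple from
#'   firing the detector on quiet traces).
#' @param search_s Forward window after a threshold crossing inside which
#'   the envelope maximum marks the QRS, in seconds.
#' @param refractory_init_s Initial QRS refractory period in seconds.
#' @param refractory_frac QRS refractory as a fraction of the running
#'   median interbeat interval.
#' @param p_highpass_hz High-pass corner removing baseline wander from the
#'   P-detection signal, in Hz.
#' @param p_smooth_s Moving-average window smoothing the P-detection
#'   signal, in seconds.
#' @param k_p Threshold multiplier on the rolling median absolute
#'   deviation of the P-detection signal.
#' @param p_refractory_s Minimum spacing between standalone P detections,
#'   in seconds.
#' @param p_window Search window for the anchored P, in seconds before the
#'   R peak: `c(earliest, latest)`.
#' @param baseline_window Local isoelectric window used for amplitude
#'   measurements, in seconds before the peak: `c(earliest, latest)`.
#' @param qrs_search_s Half-width of the QRS delineation search, seconds.
#' @param qrs_frac Fraction of the R height below which the signal is
#'   considered to have returned to baseline.
#' @param qrs_sustain_s Time the signal must stay below `qrs_frac` for the
#'   onset/offset to be accepted, in seconds.
#' @return A `detector_params` list.
#' @export
detector_params <- function(bp_low = 5, bp_high = 40, k_r = 4,
                            env_smooth_s = 0.03, env_floor_frac = 0.05,
                            search_s = 0.15,
                            refractory_init_s = 0.2, refractory_frac = 0.4,
                            p_highpass_hz = 0.7, p_smooth_s = 0.008, k_p = 4,
                            p_refractory_s = 0.25,
                            p_window = c(0.15, 0.03),
                            baseline_window = c(0.20, 0.15),
                            qrs_search_s = 0.10, qrs_frac = 0.10,
                            qrs_sustain_s = 0.004) {
  structure(
    list(bp_low = bp_low, bp_high = bp_high, k_r = k_r,
         env_smooth_s = env_smooth_s, env_floor_frac = env_floor_frac,
         search_s = search_s,
         refractory_init_s = refractory_init_s, refractory_frac = refractory_frac,
         p_highpass_hz = p_highpass_hz, p_smooth_s = p_smooth_s, k_p = k_p,
         p_refractory_s = p_refractory_s, p_window = p_window,
         baseline_window = baseline_window,
         qrs_search_s = qrs_search_s, qrs_frac = qrs_frac,
         qrs_sustain_s = qrs_sustain_s),
    class = "detector_params"
  )
}

check_trace <- function(trace, min_s = 2) {
  v <- trace$voltage_mV
  fs <- ecg_fs(trace)
  if (all(is.na(v)) || isTRUE(stats::sd(v, na.rm = TRUE) == 0)) {
    abort_zfecg("Trace carries no signal (flat or all-NA voltage).", "zfecg_no_signal")
  }
  if (length(v) < min_s * fs) {
    abort_zfecg(sprintf("Trace must be at least %g s long.", min_s), "zfecg_input")
  }
  invisible(TRUE)
}

# median of the raw signal in a window [t_peak - w[1], t_peak - w[2]];
# local isoelectric level used for amplitude measurements
local_baseline <- function(v, fs, peak_idx, window) {
  i0 <- peak_idx - round(window[1] * fs)
  i1 <- peak_idx - round(window[2] * fs)
  if (i0 < 1 || i1 < i0) return(stats::median(v))
  stats::median(v[i0:i1])
}

#' Detect R peaks in a single-lead trace
#'
#' Energy-based QRS detector: the trace is band-pass filtered, the squared
#' derivative is smoothed into an envelope, and an adaptive threshold
#' (`k_r` times the rolling median of the envelope, floored at a small
#' fraction of its 95th percentile) marks candidate complexes. Within a
#' short window after each qualifying crossing the envelope maximum
#' locates the complex and the R time is refined to the raw-signal maximum
#' within 25 ms. A refractory period equal to `refractory_frac` times the
#' running median interbeat interval suppresses double firing. Amplitudes
#' are measured from the local isoelectric baseline (the median of the raw
#' signal in `baseline_window` before the peak).
#'
#' On recordings without a usable QRS (the severe mutant phenotype) the
#' detector fires on whatever deflection dominates the envelope; such
#' detections fail to pair with a preceding P wave in [assemble_beats()],
#' which is what routes those recordings to the P-only pathway.
#'
#' @param trace An `ecg_trace` of at least 2 s.
#' @param params A [detector_params()].
#' @return A tibble with columns `time_s` and `amp_mV`, one row per
#'   detection, ordered in time.
#' @export
detect_r_peaks <- function(trace, params = detector_params()) {
  check_trace(trace)
  v <- trace$voltage_mV
  fs <- ecg_fs(trace)
  n <- length(v)

  bp <- bandpass(v, fs, params$bp_low, params$bp_high)
  d <- c(0, diff(bp)) * fs
  env <- moving_average(d^2, round(params$env_smooth_s * fs))

  thr <- params$k_r * stats::runmed(env, odd_window(2 * fs))
  floor_ <- params$env_floor_frac * stats::quantile(env, 0.95, names = FALSE)
  above <- env > pmax(thr, floor_)
  crossings <- which(diff(c(FALSE, above)) == 1L)
  if (length(crossings) == 0) {
    return(tibble::tibble(time_s = numeric(0), amp_mV = numeric(0)))
  }

  half25 <- round(0.025 * fs)
  r_idx <- integer(0)
  last_t <- -Inf
  refr <- params$refractory_init_s
  ibis <- numeric(0)

  for (c0 in crossings) {
    if ((c0 - 1) / fs - last_t < refr - params$search_s) next
    win <- c0:min(c0 + round(params$search_s * fs), n)
    # the QRS is the last substantial energy lobe in the window: a P wave
    # that crosses the threshold is followed by its QRS, while a strongly
    # suppressed QRS stays below the 40% gate and the P lobe itself wins
    seg_hi <- env[win] >= 0.4 * max(env[win])
    runs <- rle(seg_hi)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- max(which(runs$values))
    seg <- win[starts[k]:ends[k]]
    pk <- seg[which.max(env[seg])]
    lo <- max(1L, pk - half25)
    hi <- min(n, pk + half25)
    ri <- (lo:hi)[which.max(v[lo:hi])]
    rt <- (ri - 1) / fs
    if (rt - last_t < refr) next
    if (length(r_idx) > 0) {
      ibis <- c(ibis, rt - last_t)
      recent <- tail(ibis, 8)
      refr <- max(0.1, params$refractory_frac * stats::median(recent))
    }
    r_idx <- c(r_idx, ri)
    last_t <- rt
  }

  amp <- vapply(r_idx, function(i) {
    v[i] - local_baseline(v, fs, i, params$baseline_window)
  }, numeric(1))

  tibble::tibble(time_s = (r_idx - 1) / fs, amp_mV = amp)
}

# detrended, lightly smoothed signal used for all P-wave work; a rolling
# median re-references the result to the local isoelectric baseline so
# peak heights are comparable against a zero level
p_signal <- function(v, fs, params) {
  hp <- signal::butter(2, params$p_highpass_hz / (fs / 2), type = "high")
  x <- moving_average(signal::filtfilt(hp, v), round(params$p_smooth_s * fs))
  as.numeric(x - stats::runmed(x, odd_window(0.45 * fs)))
}

# rolling MAD of the P-detection signal, evaluated blockwise (5 s blocks)
# and interpolated; adapts the P threshold to slow changes in noise level
rolling_mad <- function(x, fs, block_s = 5) {
  n <- length(x)
  bl <- max(1L, round(block_s * fs))
  starts <- seq(1L, n, by = bl)
  mids <- pmin(starts + bl %/% 2L, n)
  vals <- vapply(starts, function(s) stats::mad(x[s:min(s + bl - 1L, n)]), numeric(1))
  if (length(vals) == 1L) return(rep(vals, n))
  stats::approx(mids, vals, xout = seq_len(n), rule = 2)$y
}

#' Detect P waves, with or without R-peak anchors
#'
#' P detection works on a detrended, lightly smoothed copy of the trace:
#' a high-pass removes baseline wander and a short moving average damps
#' measurement noise while leaving the P deflection essentially intact.
#' With `r_peaks` supplied, the P wave for each beat is the interior
#' maximum of that signal in the window `[r - p_window[1], r -
#' p_window[2]]`, provided it clears the adaptive threshold; windows that
#' overlap the trace boundary or contain no qualifying peak are skipped.
#' Without anchors (the pathway used when no QRS is distinguishable) P
#' waves are found by peak picking with an adaptive height threshold of
#' `k_p` times the rolling median absolute deviation and a short
#' refractory period (`p_refractory_s`, chosen below the shortest
#' physiological interbeat interval); when two candidate peaks fall within the refractory
#' distance the more prominent one wins, which is what suppresses T waves
#' and residual QRS deflections. Amplitudes are measured from the local
#' isoelectric baseline before the P peak.
#'
#' @param trace An `ecg_trace` of at least 2 s.
#' @param r_peaks Optional tibble from [detect_r_peaks()].
#' @param params A [detector_params()].
#' @return A tibble with columns `time_s` and `amp_mV`, ordered in time.
#' @export
detect_p_waves <- function(trace, r_peaks = NULL, params = detector_params()) {
  check_trace_p(trace)
  v <- trace$voltage_mV
  fs <- ecg_fs(trace)
  n <- length(v)

  lp <- p_signal(v, fs, params)
  thr <- params$k_p * rolling_mad(lp, fs)

  if (is.null(r_peaks)) {
    mind <- round(params$p_refractory_s * fs)
    pk <- pracma::findpeaks(lp, minpeakdistance = mind)
    if (is.null(pk)) {
      return(tibble::tibble(time_s = numeric(0), amp_mV = numeric(0)))
    }
    idx <- pk[, 2]
    idx <- sort(idx[lp[idx] > thr[idx]])
  } else {
    idx <- integer(0)
    for (rt in r_peaks$time_s) {
      i0 <- round((rt - params$p_window[1]) * fs) + 1L
      i1 <- round((rt - params$p_window[2]) * fs) + 1L
      if (i0 < 1L || i1 > n || i1 <= i0) next
      w <- i0:i1
      j <- w[which.max(lp[w])]
      # require a genuine interior local maximum above threshold
      if (j == i0 || j == i1) next
      if (lp[j] <= thr[j]) next
      idx <- c(idx, j)
    }
    idx <- sort(unique(idx))
  }

  # refine each P to the peak of a symmetrically smoothed copy of the raw
  # signal; the detection signal's high-pass distorts the peak location by
  # a sample or two, the symmetric smoother does not
  if (length(idx) > 0) {
    half <- round(0.008 * fs)
    sm <- moving_average(v, odd_window(0.007 * fs))
    idx <- vapply(idx, function(i) {
      w <- max(1L, i - half):min(n, i + half)
      w[which.max(sm[w])]
    }, integer(1))
    idx <- sort(unique(idx))
  }

  amp <- vapply(idx, function(i) {
    v[i] - local_baseline(v, fs, i, params$baseline_window)
  }, numeric(1))

  tibble::tibble(time_s = (idx - 1) / fs, amp_mV = amp)
}

# P detection tolerates flat traces (empty result) but still needs length
check_trace_p <- function(trace, min_s = 2) {
  fs <- ecg_fs(trace)
  if (all(is.na(trace$voltage_mV))) {
    abort_zfecg("Trace carries no signal (all-NA voltage).", "zfecg_no_signal")
  }
  if (length(trace$voltage_mV) < min_s * fs) {
    abort_zfecg(sprintf("Trace must be at least %g s long.", min_s), "zfecg_input")
  }
  invisible(TRUE)
}

#' Delineate QRS onset and offset around detected R peaks
#'
#' Starting at each R peak, the onset (offset) is the first sample moving
#' left (right) at which the absolute deviation of the raw signal from the
#' local isoelectric baseline stays below `qrs_frac` of the R height for
#' at least `qrs_sustain_s`. Beats for which the search reaches the window
#' edge without settling are flagged with `NA` and excluded from
#' QRS-duration averages downstream.
#'
#' @param trace An `ecg_trace`.
#' @param r_peaks Nonempty tibble from [detect_r_peaks()].
#' @param params A [detector_params()].
#' @return A tibble with columns `r_time_s`, `onset_s` and `offset_s`
#'   (`NA` for flagged beats).
#' @export
delineate_qrs <- function(trace, r_peaks, params = detector_params()) {
  if (is.null(r_peaks) || nrow(r_peaks) == 0) {
    abort_zfecg("`r_peaks` must contain at least one detection.", "zfecg_input")
  }
  v <- trace$voltage_mV
  fs <- ecg_fs(trace)
  n <- length(v)
  sustain <- max(1L, round(params$qrs_sustain_s * fs))
  wlen <- round(params$qrs_search_s * fs)

  res <- lapply(r_peaks$time_s, function(rt) {
    ri <- round(rt * fs) + 1L
    base <- local_baseline(v, fs, ri, params$baseline_window)
    h <- abs(v[ri] - base)
    if (h == 0) return(c(NA_real_, NA_real_))
    below <- function(i) abs(v[i] - base) < params$qrs_frac * h

    find_edge <- function(dir) {
      run <- 0L
      steps <- seq_len(wlen)
      for (s in steps) {
        i <- ri + dir * s
        if (i < 1L || i > n) return(NA_real_)
        if (below(i)) {
          run <- run + 1L
          if (run >= sustain) {
            edge <- i - dir * (run - 1L)  # first below-threshold sample
            return((edge - dir - 1) / fs) # last above-threshold sample
          }
        } else {
          run <- 0L
        }
      }
      NA_real_
    }

    c(find_edge(-1L), find_edge(1L))
  })
  m <- do.call(rbind, res)
  tibble::tibble(r_time_s = r_peaks$time_s, onset_s = m[, 1], offset_s = m[, 2])
}

#' Assemble P, R and QRS detections into a beat table
#'
#' Each P wave is paired with the first following R peak whose lag falls
#' in (0.01, 0.2) s; each R pairs with at most one P. Unpaired P waves
#' become beats with `qrs_detected = FALSE` (the P-only pathway); unpaired
#' R detections are discarded with a warning.
#'
#' @param p_list,r_list Tibbles with `time_s` and `amp_mV` columns,
#'   time-sorted. `r_list` may be `NULL` or empty.
#' @param qrs_list Optional tibble from [delineate_qrs()] aligned with
#'   `r_list`.
#' @param trace The `ecg_trace` the detections came from (supplies the
#'   recording duration).
#' @return A `beat_set`: a tibble with columns `beat_idx`, `p_time_s`,
#'   `p_amp_mV`, `qrs_onset_s`, `r_time_s`, `r_amp_mV`, `qrs_offset_s` and
#'   `qrs_detected`, with attribute `trace_duration_s`.
#' @export
assemble_beats <- function(p_list, r_list = NULL, qrs_list = NULL, trace = NULL) {
  if (is.null(r_list)) r_list <- tibble::tibble(time_s = numeric(0), amp_mV = numeric(0))
  np <- nrow(p_list)
  nr <- nrow(r_list)

  pair_of_p <- rep(NA_integer_, np)
  used_r <- rep(FALSE, nr)
  for (i in seq_len(np)) {
    lag <- r_list$time_s - p_list$time_s[i]
    cand <- which(lag > 0.01 & lag < 0.2 & !used_r)
    if (length(cand) > 0) {
      j <- cand[which.min(lag[cand])]
      pair_of_p[i] <- j
      used_r[j] <- TRUE
    }
  }
  n_dropped <- sum(!used_r)
  if (n_dropped > 0) {
    rlang::warn(sprintf("Discarded %d R detection(s) with no P wave within 0.2 s.", n_dropped),
                class = "zfecg_unpaired_r")
  }

  get_r <- function(col) {
    out <- rep(NA_real_, np)
    ok <- !is.na(pair_of_p)
    out[ok] <- r_list[[col]][pair_of_p[ok]]
    out
  }
  get_q <- function(col) {
    out <- rep(NA_real_, np)
    if (is.null(qrs_list)) return(out)
    ok <- !is.na(pair_of_p)
    out[ok] <- qrs_list[[col]][pair_of_p[ok]]
    out
  }

  beats <- tibble::tibble(
    beat_idx = seq_len(np),
    p_time_s = p_list$time_s,
    p_amp_mV = p_list$amp_mV,
    qrs_onset_s = get_q("onset_s"),
    r_time_s = get_r("time_s"),
    r_amp_mV = get_r("amp_mV"),
    qrs_offset_s = get_q("offset_s"),
    qrs_detected = !is.na(pair_of_p)
  )
  dur <- if (!is.null(trace)) length(trace$voltage_mV) / ecg_fs(trace) else NA_real_
  attr(beats, "trace_duration_s") <- dur
  class(beats) <- c("beat_set", class(beats))
  beats
}

#' Run the full beat-detection pipeline on one trace
#'
#' Runs the QRS detector and the anchored P search; when at least half of
#' the R detections have an identifiable preceding P wave the recording is
#' treated as having a distinguishable QRS and beats carry full fiducials
#' (P, QRS onset, R, QRS offset). Otherwise the recording is analyzed
#' through the P-only pathway: standalone P detection with
#' `qrs_detected = FALSE` throughout.
#'
#' @param trace An `ecg_trace`.
#' @param params A [detector_params()].
#' @return A `beat_set` (see [assemble_beats()]).
#' @examples
#' rec <- simulate_ecg(wt_config(duration_s = 6, seed = 2))
#' nrow(detect_beats(rec$trace))
#' @export
detect_beats <- function(trace, params = detector_params()) {
  r <- detect_r_peaks(trace, params)
  p_anchored <- if (nrow(r) > 0) detect_p_waves(trace, r, params) else r
  anchored_frac <- if (nrow(r) > 0) nrow(p_anchored) / nrow(r) else 0

  if (nrow(r) >= 3 && anchored_frac >= 0.5) {
    qrs <- delineate_qrs(trace, r, params)
    assemble_beats(p_anchored, r, qrs, trace)
  } else {
    p <- detect_p_waves(trace, NULL, params)
    assemble_beats(p, NULL, NULL, trace)
  }
}
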