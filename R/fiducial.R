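# R-peak detection and P/Q/S/T delineation.
#
# The detector is a Pan-Tompkins style chain: band-pass 5-15 Hz, first
# difference, squaring, 150 ms moving-window integration, adaptive
# thresholding with a 200 ms refractory period, and final refinement of each
# peak to the local extremum of the raw signal. It stands in for published
# QRS detectors with the same interface contract (strictly increasing
# indices, refractory spacing). Delineation uses fixed physiologic search
# windows around each R peak; all windows are config-overridable.

#' Default delineation windows (milliseconds)
#'
#' Search windows around the R peak used by [delineate_waves()]: Q and S are
#' the signal minima within `q_ms`/`s_ms` of R; P is the maximum in the
#' `p_ms` interval before R; T is the maximum in the `t_ms` interval after R,
#' truncated at the next beat and flagged absent when the remaining window is
#' shorter than `t_min_ms`.
#'
#' @return Named list of window bounds in ms.
#' @export
delineation_windows <- function() {
  list(q_ms = 50, s_ms = 50, p_ms = c(200, 80), t_ms = c(80, 400),
       t_min_ms = 40)
}

#' Detect R peaks in a single-lead ECG
#'
#' @param x Numeric vector, one lead in millivolts.
#' @param fs Sampling frequency in Hz.
#' @param refractory_s Minimum peak spacing in seconds (default 0.2).
#' @return Integer vector of strictly increasing sample indices; empty for a
#'   flat signal.
#' @examples
#' rec <- generate_record(rhythm_spec("Normal", 60, rr_jitter = 0),
#'                        duration_s = 10, noise_sd = 0, seed = 1)
#' detect_r_peaks(rec$signal["II", ], rec$fs)
#' @export
detect_r_peaks <- function(x, fs, refractory_s = 0.2) {
  assert_scalar_num(fs, "fs", 1e-9)
  if (length(x) < 2 * fs) stopf("signal shorter than 2 s: too little data for QRS detection")
  if (stats::sd(x) < 1e-12) return(integer(0))

  nyq <- fs / 2
  bp <- signal::butter(2, c(5, 15) / nyq, type = "pass")
  xf <- signal::filtfilt(bp, x - mean(x))
  d <- c(diff(xf), 0)
  sq <- d^2
  win <- max(1L, round(0.150 * fs))
  integ <- moving_sum(sq, win) / win

  # Adaptive threshold: a fraction of a running amplitude estimate; the
  # running estimate follows the median of the top integrated-peak heights.
  thr <- 0.20 * max(integ)
  above <- integ > thr
  # candidate regions of consecutive above-threshold samples
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (i in which(r$values)) {
    seg <- starts[i]:ends[i]
    cand <- c(cand, seg[which.max(integ[seg])])
  }
  if (!length(cand)) return(integer(0))

  # refractory: greedy keep of the larger peak within 200 ms
  keep <- integer(0)
  refr <- round(refractory_s * fs)
  for (c0 in cand) {
    if (length(keep) && c0 - keep[length(keep)] < refr) {
      if (integ[c0] > integ[keep[length(keep)]]) keep[length(keep)] <- c0
    } else {
      keep <- c(keep, c0)
    }
  }

  # refine to the raw-signal extremum near each integrated peak; the
  # integrator delays peaks by about half its window
  half <- round(0.100 * fs)
  peaks <- vapply(keep, function(c0) {
    lo <- max(1L, c0 - half - win %/% 2L)
    hi <- min(length(x), c0 + half)
    seg <- lo:hi
    seg[which.max(abs(x[seg] - stats::median(x)))]
  }, integer(1))
  peaks <- sort(unique(peaks))

  # re-apply refractory on refined indices
  if (length(peaks) > 1) {
    out <- peaks[1]
    for (p in peaks[-1]) {
      if (p - out[length(out)] >= refr) {
        out <- c(out, p)
      } else if (abs(x[p]) > abs(x[out[length(out)]])) {
        out[length(out)] <- p
      }
    }
    peaks <- out
  }
  as.integer(peaks)
}

#' Delineate P, Q, S and T waves around detected R peaks
#'
#' Q and S are signal minima in short windows flanking R; P is the maximum
#' in a `[-200, -80]` ms pre-R window; T the maximum in an `[80, 400]` ms
#' post-R window truncated at the next beat. A wave is flagged absent (`NA`)
#' when its search window is empty or, for T, shorter than 40 ms.
#'
#' @param x Single-lead signal (mV).
#' @param fs Sampling frequency (Hz).
#' @param r_idx R-peak sample indices, as from [detect_r_peaks()].
#' @param windows Window bounds, see [delineation_windows()].
#' @return A `fiducial_points` tibble: one row per beat with columns `beat`,
#'   `p`, `q`, `r`, `s`, `t` (sample indices, `NA` when absent) and
#'   attribute `fs`.
#' @export
delineate_waves <- function(x, fs, r_idx, windows = delineation_windows()) {
  if (any(r_idx < 1 | r_idx > length(x))) stopf("`r_idx` out of signal bounds")
  if (is.unsorted(r_idx, strictly = TRUE)) stopf("`r_idx` must be strictly increasing")
  ms <- function(v) round(v / 1000 * fs)
  n <- length(x)
  rows <- purrr::map(seq_along(r_idx), function(i) {
    r <- r_idx[i]
    win_pick <- function(lo, hi, fun) {
      lo <- max(1L, lo); hi <- min(n, hi)
      if (lo > hi) return(NA_integer_)
      seg <- lo:hi
      seg[fun(x[seg])]
    }
    q <- win_pick(r - ms(windows$q_ms), r - 1L, which.min)
    s <- win_pick(r + 1L, r + ms(windows$s_ms), which.min)
    p <- win_pick(r - ms(windows$p_ms[1]), r - ms(windows$p_ms[2]), which.max)
    t_hi <- r + ms(windows$t_ms[2])
    if (i < length(r_idx)) t_hi <- min(t_hi, r_idx[i + 1] - ms(windows$q_ms) - 1L)
    t_lo <- r + ms(windows$t_ms[1])
    t <- if (min(n, t_hi) - t_lo < ms(windows$t_min_ms)) NA_integer_ else {
      win_pick(t_lo, t_hi, which.max)
    }
    tibble::tibble(beat = i, p = p, q = q, r = as.integer(r), s = s, t = t)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fs") <- fs
  class(out) <- c("fiducial_points", class(out))
  out
}

#' Detect and delineate in one step
#'
#' Runs [detect_r_peaks()] then [delineate_waves()] on one lead of a record.
#'
#' @param record An `ecg_record`.
#' @param lead Lead name (default `"II"`).
#' @param windows Delineation windows.
#' @return A `fiducial_points` tibble.
#' @export
find_fiducials <- function(record, lead = "II",
                           windows = delineation_windows()) {
  x <- record$signal[lead, ]
  r_idx <- detect_r_peaks(x, record$fs)
  if (!length(r_idx)) {
    out <- tibble::tibble(beat = integer(), p = integer(), q = integer(),
                          r = integer(), s = integer(), t = integer())
    attr(out, "fs") <- record$fs
    class(out) <- c("fiducial_points", class(out))
    return(out)
  }
  delineate_waves(x, record$fs, r_idx, windows)
}

#' Score R-peak detection against ground truth
#'
#' Matches detected peaks to reference peaks greedily within a tolerance and
#' reports sensitivity (fraction of reference beats found) and positive
#' predictivity (fraction of detections that are true).
#'
#' @param detected,truth Sample-index vectors.
#' @param fs Sampling frequency (Hz).
#' @param tol_s Matching tolerance in seconds (default 0.05, i.e. 50 ms).
#' @return Tibble with `n_true`, `n_detected`, `tp`, `sensitivity`, `ppv`.
#' @export
score_r_detection <- function(detected, truth, fs, tol_s = 0.05) {
  tol <- tol_s * fs
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (t0 in truth) {
    d <- abs(detected - t0)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      tp <- tp + 1L
    }
  }
  tibble::tibble(
    n_true = length(truth), n_detected = length(detected), tp = tp,
    sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
    ppv = if (length(detected)) tp / length(detected) else NA_real_
  )
}
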