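# The 118-attribute ECG feature catalog and its extractors.
#
# Four families with locked counts: 27 time-domain (RR-interval statistics),
# 35 frequency-domain (periodogram band powers, spectral shape statistics,
# Haar wavelet sub-band energies), 30 morphological (per-beat wave
# amplitudes/intervals aggregated as mean and SD) and 26 nonlinear
# (sample/approximate/fuzzy entropy over an (m, r) grid, Poincare geometry,
# detrended fluctuation, fractal dimensions, Hjorth parameters,
# Lempel-Ziv complexity). Only a handful of members are canonical
# (RR min/max, median heart rate, RMSSD, normalized LF/HF power, S/Q/R
# depths, ST slope, QRS width, sample/approximate/fuzzy entropy); the rest
# are catalog-fill drawn from standard HRV/spectral/morphology/complexity
# practice to reach the fixed family sizes. Undefined values (too few beats,
# degenerate windows) become NA and are median-imputed at the design-matrix
# stage, never silently propagated.

.time_names <- c(
  "rr_mean", "rr_min", "rr_max", "rr_median", "rr_sd", "rr_range", "rr_iqr",
  "rr_cv", "rr_mad", "rr_p5", "rr_p25", "rr_p75", "rr_p95", "rr_skewness",
  "rr_kurtosis", "rmssd", "sdsd", "pnn50", "pnn20", "rr_diff_mean_abs",
  "rr_diff_max_abs", "hr_mean", "hr_min", "hr_max", "hr_median", "hr_sd",
  "beat_rate"
)

.freq_names <- c(
  "total_power",
  paste0("bp_", 1:6), paste0("bpn_", 1:6),
  "lf_norm", "hf_norm", "lf_hf_ratio",
  "spectral_centroid", "spectral_spread", "spectral_skewness",
  "spectral_kurtosis", "spectral_entropy", "spectral_flatness",
  "spectral_rolloff85", "spectral_rolloff95", "peak_freq", "median_freq",
  "spectral_crest",
  paste0("wav_e_d", 1:4), "wav_e_a4", paste0("wav_rel_d", 1:3)
)

.morph_quantities <- c(
  "r_amp", "q_amp", "s_amp", "p_amp", "t_amp", "qrs_width", "qr_interval",
  "rs_interval", "pr_interval", "qt_interval", "st_slope", "st_level",
  "rs_amp_ratio", "tr_amp_ratio", "pr_amp_ratio"
)
.morph_names <- c(paste0(.morph_quantities, "_mean"),
                  paste0(.morph_quantities, "_sd"))

.nonlin_names <- c(
  "sampen_rr_r15", "sampen_rr_r20", "sampen_rr_r25",
  "apen_rr_r15", "apen_rr_r20", "apen_rr_r25",
  "fuzzen_rr_r15", "fuzzen_rr_r20", "fuzzen_rr_r25",
  "poincare_sd1", "poincare_sd2", "poincare_ratio", "poincare_area",
  "sampen_sig", "apen_sig", "fuzzen_sig",
  "dfa_alpha1", "higuchi_fd", "katz_fd", "petrosian_fd",
  "hjorth_mobility", "hjorth_complexity", "lz_complexity",
  "zero_cross_rate", "shannon_entropy_rr", "renyi2_entropy_rr"
)

#' The locked 118-attribute feature catalog
#'
#' Names, family and unit of every feature, in the frozen extraction order
#' time-domain (27), frequency-domain (35), morphological (30),
#' nonlinear (26).
#'
#' @return Tibble with columns `name`, `category`, `unit`, `index`.
#' @examples
#' dplyr::count(feature_catalog(), category)
#' @export
feature_catalog <- function() {
  unit_of <- function(nm) {
    dplyr::case_when(
      grepl("^(rr_|rmssd|sdsd|qrs_width|.*_interval)", nm) &
        !grepl("ratio|pnn|skew|kurt|cv", nm) ~ "s",
      grepl("^hr_|beat_rate", nm) ~ "bpm",
      grepl("^(bp_|total_power|wav_e_)", nm) ~ "mV^2",
      grepl("freq$|centroid|spread|rolloff", nm) ~ "Hz",
      grepl("_amp_mean|_amp_sd|amp$|st_level", nm) ~ "mV",
      grepl("st_slope", nm) ~ "mV/s",
      TRUE ~ "dimensionless"
    )
  }
  cat_tbl <- tibble::tibble(
    name = c(.time_names, .freq_names, .morph_names, .nonlin_names),
    category = rep(c("time_domain", "frequency_domain", "morphological",
                     "nonlinear"),
                   times = c(length(.time_names), length(.freq_names),
                             length(.morph_names), length(.nonlin_names)))
  )
  cat_tbl$unit <- unit_of(cat_tbl$name)
  cat_tbl$index <- seq_len(nrow(cat_tbl))
  cat_tbl
}

# ---- time domain ----------------------------------------------------------

.skewness <- function(x) {
  s <- stats::sd(x)
  if (s < 1e-12) return(0)
  mean((x - mean(x))^3) / s^3
}
.kurtosis <- function(x) {
  s <- stats::sd(x)
  if (s < 1e-12) return(0)
  mean((x - mean(x))^4) / s^4
}

#' Time-domain heart-rate-variability features
#'
#' 27 statistics of the RR-interval series derived from the R-peak times:
#' location and spread (min, max, mean, median, SD, range, IQR, CV, MAD,
#' percentiles, skewness, kurtosis), successive-difference measures (RMSSD,
#' SDSD, pNN50, pNN20) and instantaneous heart-rate statistics.
#'
#' @param fiducials A `fiducial_points` tibble (needs >= 3 beats) or a
#'   numeric vector of RR intervals in seconds (>= 2 intervals).
#' @param fs Sampling frequency; required when `fiducials` is a tibble.
#' @param duration_s Record duration, for the beat-rate feature; inferred
#'   from the beat span when missing.
#' @return Named numeric vector of length 27.
#' @export
extract_time_domain <- function(fiducials, fs = NULL, duration_s = NULL) {
  if (is.numeric(fiducials)) {
    rr <- fiducials
  } else {
    if (nrow(fiducials) < 3) stopf("need at least 3 beats for RR statistics")
    rr <- diff(fiducials$r) / (fs %||% attr(fiducials, "fs"))
  }
  if (length(rr) < 2) stopf("need at least 2 RR intervals")
  drr <- diff(rr)
  hr <- 60 / rr
  dur <- duration_s %||% (sum(rr) + mean(rr))
  q <- stats::quantile(rr, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
  out <- c(
    rr_mean = mean(rr), rr_min = min(rr), rr_max = max(rr),
    rr_median = stats::median(rr), rr_sd = stats::sd(rr),
    rr_range = max(rr) - min(rr), rr_iqr = q[3] - q[2],
    rr_cv = stats::sd(rr) / mean(rr), rr_mad = stats::mad(rr),
    rr_p5 = q[1], rr_p25 = q[2], rr_p75 = q[3], rr_p95 = q[4],
    rr_skewness = .skewness(rr), rr_kurtosis = .kurtosis(rr),
    rmssd = sqrt(mean(drr^2)),
    sdsd = if (length(drr) > 1) stats::sd(drr) else 0,
    pnn50 = mean(abs(drr) > 0.05), pnn20 = mean(abs(drr) > 0.02),
    rr_diff_mean_abs = mean(abs(drr)), rr_diff_max_abs = max(abs(drr)),
    hr_mean = mean(hr), hr_min = min(hr), hr_max = max(hr),
    hr_median = stats::median(hr), hr_sd = stats::sd(hr),
    beat_rate = (length(rr) + 1) / dur * 60
  )
  names(out) <- .time_names
  out
}

# ---- frequency domain -----------------------------------------------------

# Minimal Haar DWT pyramid: returns detail coefficient vectors d1..dL and
# the final approximation. Signal length is truncated to even at each level.
.haar_dwt <- function(x, levels = 4L) {
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    n <- length(a) %/% 2L * 2L
    if (n < 2L) {
      details[[l]] <- numeric(0)
      next
    }
    a <- a[seq_len(n)]
    even <- a[seq(2, n, by = 2)]
    odd <- a[seq(1, n, by = 2)]
    details[[l]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(details = details, approx = a)
}

#' Frequency-domain features of a signal window
#'
#' 35 spectral statistics of one lead window: total power, absolute and
#' normalized power in six fixed bands (0.5-4, 4-10, 10-15, 15-25, 25-40 and
#' 40-Nyquist Hz), normalized low/high-frequency power (LF 0.5-10 Hz,
#' HF 10-40 Hz) and their ratio, spectral shape statistics of the
#' periodogram (centroid, spread, skewness, kurtosis, entropy, flatness,
#' roll-offs, peak and median frequency, crest factor) and 4-level Haar
#' wavelet sub-band energies (absolute and relative). An all-zero window
#' yields zero band powers with shape statistics flagged `NA`.
#'
#' @param x Numeric signal window (>= 1 s of samples).
#' @param fs Sampling frequency in Hz.
#' @return Named numeric vector of length 35.
#' @export
extract_frequency_domain <- function(x, fs) {
  if (length(x) < fs) stopf("window shorter than 1 s")
  n35 <- length(.freq_names)
  if (stats::sd(x) < 1e-14) {
    out <- rep(NA_real_, n35)
    names(out) <- .freq_names
    out[c("total_power", paste0("bp_", 1:6),
          paste0("wav_e_d", 1:4), "wav_e_a4")] <- 0
    return(out)
  }
  x0 <- x - mean(x)
  n <- length(x0)
  spec <- Mod(stats::fft(x0))^2 / n
  half <- seq_len(n %/% 2 + 1)
  p <- spec[half]
  f <- (half - 1) * fs / n
  ptot <- sum(p)
  pn <- p / ptot

  nyq <- fs / 2
  edges <- c(0.5, 4, 10, 15, 25, 40, max(41, nyq))
  bp <- vapply(seq_len(6), function(i) {
    sum(p[f >= edges[i] & f < min(edges[i + 1], nyq + 1e-9)])
  }, numeric(1))
  in_band <- sum(bp)
  bpn <- if (in_band > 0) bp / in_band else rep(0, 6)
  lf <- sum(p[f >= 0.5 & f < 10])
  hf <- sum(p[f >= 10 & f < 40])
  lfhf_tot <- lf + hf

  centroid <- sum(f * pn)
  spread <- sqrt(sum((f - centroid)^2 * pn))
  sskew <- if (spread > 1e-12) sum((f - centroid)^3 * pn) / spread^3 else 0
  skurt <- if (spread > 1e-12) sum((f - centroid)^4 * pn) / spread^4 else 0
  sent <- -sum(ifelse(pn > 0, pn * log(pn), 0)) / log(length(pn))
  pos <- p[p > 1e-300]
  flat <- exp(mean(log(pos))) / mean(pos)
  cum <- cumsum(pn)
  roll85 <- f[which(cum >= 0.85)[1]]
  roll95 <- f[which(cum >= 0.95)[1]]
  fpeak <- f[which.max(p)]
  fmed <- f[which(cum >= 0.5)[1]]
  crest <- max(p) / mean(p)

  dw <- .haar_dwt(x0, 4L)
  we <- vapply(dw$details, function(d) sum(d^2), numeric(1))
  wa <- sum(dw$approx^2)
  wtot <- sum(we) + wa
  wrel <- if (wtot > 0) we[1:3] / wtot else rep(0, 3)

  out <- c(ptot, bp, bpn,
           if (lfhf_tot > 0) lf / lfhf_tot else NA_real_,
           if (lfhf_tot > 0) hf / lfhf_tot else NA_real_,
           if (hf > 0) lf / hf else NA_real_,
           centroid, spread, sskew, skurt, sent, flat, roll85, roll95,
           fpeak, fmed, crest, we, wa, wrel)
  names(out) <- .freq_names
  out
}

# ---- morphological --------------------------------------------------------

#' Morphological features from delineated beats
#'
#' 30 statistics: the mean and SD over beats of 15 per-beat quantities —
#' wave amplitudes (R, Q, S, P, T), QRS width and sub-intervals, PR and QT
#' intervals, ST-segment slope and level, and amplitude ratios. Beats
#' missing Q, R or S are skipped; quantities needing P or T are `NA` for
#' beats where that wave is absent.
#'
#' @param x Single-lead signal (mV).
#' @param fiducials A `fiducial_points` tibble.
#' @param fs Sampling frequency; defaults to the tibble's `fs` attribute.
#' @return Named numeric vector of length 30.
#' @export
extract_morphological <- function(x, fiducials, fs = NULL) {
  fs <- fs %||% attr(fiducials, "fs")
  fid <- dplyr::filter(fiducials, !is.na(.data$q), !is.na(.data$r), !is.na(.data$s))
  if (nrow(fid) < 1) stopf("no complete beat with Q, R and S present")
  base <- stats::median(x)
  per_beat <- purrr::map_dfr(seq_len(nrow(fid)), function(i) {
    b <- fid[i, ]
    r_amp <- x[b$r] - base
    q_amp <- x[b$q] - base
    s_amp <- x[b$s] - base
    p_amp <- if (!is.na(b$p)) x[b$p] - base else NA_real_
    t_amp <- if (!is.na(b$t)) x[b$t] - base else NA_real_
    # ST segment: 40-120 ms after S
    st_lo <- b$s + round(0.04 * fs)
    st_hi <- min(length(x), b$s + round(0.12 * fs))
    st_slope <- st_level <- NA_real_
    if (st_hi - st_lo >= 2) {
      seg <- x[st_lo:st_hi]
      tt <- (seq_along(seg) - 1) / fs
      cf <- stats::coef(stats::lm.fit(cbind(1, tt), seg))
      st_slope <- cf[2]
      st_level <- mean(seg) - base
    }
    tibble::tibble(
      r_amp = r_amp, q_amp = q_amp, s_amp = s_amp, p_amp = p_amp,
      t_amp = t_amp,
      qrs_width = (b$s - b$q) / fs,
      qr_interval = (b$r - b$q) / fs,
      rs_interval = (b$s - b$r) / fs,
      pr_interval = if (!is.na(b$p)) (b$r - b$p) / fs else NA_real_,
      qt_interval = if (!is.na(b$t)) (b$t - b$q) / fs else NA_real_,
      st_slope = st_slope, st_level = st_level,
      rs_amp_ratio = if (abs(s_amp) > 1e-9) abs(r_amp) / abs(s_amp) else NA_real_,
      tr_amp_ratio = if (abs(r_amp) > 1e-9) t_amp / r_amp else NA_real_,
      pr_amp_ratio = if (abs(r_amp) > 1e-9) p_amp / r_amp else NA_real_
    )
  })
  mu <- vapply(per_beat, function(v) mean(v, na.rm = TRUE), numeric(1))
  sdv <- vapply(per_beat, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) stats::sd(v) else 0
  }, numeric(1))
  mu[!is.finite(mu)] <- NA_real_
  out <- c(mu, sdv)
  names(out) <- .morph_names
  out
}

# ---- nonlinear ------------------------------------------------------------

# Embedding-matrix Chebyshev distances for entropy estimators. Returns the
# count of pairs (i < j) with distance <= r for embedding dimension m.
.embed_mat <- function(x, m) {
  n <- length(x) - m + 1
  if (n < 2) return(NULL)
  sapply(seq_len(m), function(k) x[k:(k + n - 1)])
}

.cheb_pairs_leq <- function(E, r) {
  # E: n x m embedding matrix; counts unordered pairs within r (Chebyshev)
  n <- nrow(E)
  cnt <- 0
  d <- matrix(0, n, n)
  for (k in seq_len(ncol(E))) {
    d <- pmax(d, abs(outer(E[, k], E[, k], "-")))
  }
  sum(d[upper.tri(d)] <= r)
}

#' Sample entropy
#'
#' SampEn(m, r): negative log of the conditional probability that two
#' sequences matching for m points (Chebyshev distance <= r, self-matches
#' excluded) also match for m + 1 points.
#'
#' @param x Numeric series (length >= 10 * m).
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; absolute unless `r_relative`, in which case `r * sd(x)`.
#' @param r_relative Interpret `r` as a multiple of `sd(x)` (default TRUE).
#' @return Nonnegative scalar; 0 for a constant series; `NA` when no
#'   m-matches exist.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2, r_relative = TRUE) {
  if (length(x) < 10 * m) stopf("series too short for embedding dimension %d", m)
  s <- stats::sd(x)
  if (s < 1e-14) return(0)
  rr <- if (r_relative) r * s else r
  Em <- .embed_mat(x, m)
  Em1 <- .embed_mat(x, m + 1L)
  # align template counts on the common n - m vectors
  n1 <- nrow(Em1)
  B <- .cheb_pairs_leq(Em[seq_len(n1), , drop = FALSE], rr)
  A <- .cheb_pairs_leq(Em1, rr)
  if (B == 0) return(NA_real_)
  if (A == 0) return(-log(1 / (n1 * (n1 - 1) / 2)))
  -log(A / B)
}

#' Approximate entropy
#'
#' ApEn(m, r) following the classical phi(m) - phi(m+1) construction with
#' self-matches included.
#'
#' @inheritParams sample_entropy
#' @return Nonnegative scalar (up to estimator bias); 0 for constant series.
#' @export
approx_entropy <- function(x, m = 2L, r = 0.2, r_relative = TRUE) {
  if (length(x) < 10 * m) stopf("series too short for embedding dimension %d", m)
  s <- stats::sd(x)
  if (s < 1e-14) return(0)
  rr <- if (r_relative) r * s else r
  phi <- function(mm) {
    E <- .embed_mat(x, mm)
    n <- nrow(E)
    d <- matrix(0, n, n)
    for (k in seq_len(ncol(E))) {
      d <- pmax(d, abs(outer(E[, k], E[, k], "-")))
    }
    Ci <- rowMeans(d <= rr)
    mean(log(Ci))
  }
  phi(m) - phi(m + 1L)
}

#' Fuzzy entropy
#'
#' FuzzyEn(m, r): like sample entropy but with an exponential membership
#' degree exp(-(d/r)^2) on baseline-removed embedding vectors instead of a
#' hard threshold.
#'
#' @inheritParams sample_entropy
#' @return Nonnegative scalar.
#' @export
fuzzy_entropy <- function(x, m = 2L, r = 0.2, r_relative = TRUE) {
  if (length(x) < 10 * m) stopf("series too short for embedding dimension %d", m)
  s <- stats::sd(x)
  if (s < 1e-14) return(0)
  rr <- if (r_relative) r * s else r
  phi <- function(mm) {
    E <- .embed_mat(x, mm)
    E <- E - rowMeans(E)
    n <- nrow(E)
    d <- matrix(0, n, n)
    for (k in seq_len(ncol(E))) {
      d <- pmax(d, abs(outer(E[, k], E[, k], "-")))
    }
    mu <- exp(-(d / rr)^2)
    (sum(mu) - n) / (n * (n - 1))
  }
  p_m <- phi(m)
  p_m1 <- phi(m + 1L)
  if (p_m <= 0 || p_m1 <= 0) return(NA_real_)
  -log(p_m1 / p_m)
}

# Detrended fluctuation analysis, short-range exponent (box sizes 4..16).
.dfa_alpha1 <- function(x) {
  n <- length(x)
  if (n < 20) return(NA_real_)
  y <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(4), log(min(16, n %/% 4)), length.out = 6))))
  sizes <- sizes[sizes >= 4]
  if (length(sizes) < 3) return(NA_real_)
  fl <- vapply(sizes, function(s) {
    nb <- n %/% s
    res <- vapply(seq_len(nb), function(b) {
      seg <- y[((b - 1) * s + 1):(b * s)]
      tt <- seq_len(s)
      fit <- stats::lm.fit(cbind(1, tt), seg)
      mean(fit$residuals^2)
    }, numeric(1))
    sqrt(mean(res))
  }, numeric(1))
  if (any(fl <= 0)) return(NA_real_)
  stats::coef(stats::lm.fit(cbind(1, log(sizes)), log(fl)))[2]
}

.higuchi_fd <- function(x, kmax = 8L) {
  n <- length(x)
  if (n < 2 * kmax) return(NA_real_)
  lk <- vapply(seq_len(kmax), function(k) {
    lm_ <- vapply(seq_len(k), function(m0) {
      idx <- seq(m0, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      sum(abs(diff(x[idx]))) * (n - 1) / (k * (length(idx) - 1)) / k
    }, numeric(1))
    mean(lm_, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(lk) & lk > 0
  if (sum(ok) < 3) return(NA_real_)
  -stats::coef(stats::lm.fit(cbind(1, log(seq_len(kmax)[ok])), log(lk[ok])))[2]
}

.katz_fd <- function(x) {
  n <- length(x)
  L <- sum(sqrt(1 + diff(x)^2))
  d <- max(sqrt((seq_len(n) - 1)^2 + (x - x[1])^2))
  if (d <= 0 || L <= 0) return(NA_real_)
  log10(n - 1) / (log10(n - 1) + log10(d / L))
}

.petrosian_fd <- function(x) {
  n <- length(x)
  dx <- diff(x)
  nd <- sum(diff(sign(dx)) != 0)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

.hjorth <- function(x) {
  dx <- diff(x)
  ddx <- diff(dx)
  v0 <- stats::var(x)
  v1 <- stats::var(dx)
  v2 <- stats::var(ddx)
  if (v0 < 1e-20 || v1 < 1e-20) return(c(NA_real_, NA_real_))
  mob <- sqrt(v1 / v0)
  c(mob, sqrt(v2 / v1) / mob)
}

# Lempel-Ziv complexity of the median-crossing binary sequence, normalized
# by n / log2(n).
.lz_complexity <- function(x) {
  b <- as.integer(x > stats::median(x))
  n <- length(b)
  if (n < 4) return(NA_real_)
  s <- paste(b, collapse = "")
  i <- 1L; c_cnt <- 0L
  dict <- new.env(hash = TRUE, parent = emptyenv())
  j <- i
  while (j <= n) {
    k <- j
    repeat {
      sub <- substr(s, j, k)
      if (is.null(dict[[sub]]) || k >= n) {
        dict[[sub]] <- TRUE
        c_cnt <- c_cnt + 1L
        j <- k + 1L
        break
      }
      k <- k + 1L
    }
  }
  c_cnt / (n / log2(n))
}

.hist_entropy <- function(x, bins = 10L, order = 1) {
  if (length(unique(x)) < 2) return(0)
  h <- tabulate(cut(x, breaks = bins, labels = FALSE), nbins = bins)
  p <- h[h > 0] / sum(h)
  if (order == 1) -sum(p * log(p)) else -log(sum(p^order)) / (order - 1)
}

#' Nonlinear complexity features
#'
#' 26 measures: sample/approximate/fuzzy entropy of the RR series over an
#' (m = 2, r in {0.15, 0.20, 0.25} sd) grid, Poincare plot geometry
#' (SD1, SD2, ratio, ellipse area), the same three entropies of a
#' downsampled signal window (m = 2, r = 0.2 sd), detrended-fluctuation
#' alpha1, Higuchi/Katz/Petrosian fractal dimensions, Hjorth mobility and
#' complexity, Lempel-Ziv complexity, zero-crossing rate, and Shannon and
#' Renyi-2 histogram entropies of the RR series. The signal is decimated to
#' about 125 Hz before the entropy/fractal estimators to keep the quadratic
#' template searches tractable.
#'
#' @param x Single-lead signal window (mV).
#' @param rr RR-interval series in seconds (>= 3 intervals for RR entropies).
#' @param fs Sampling frequency in Hz.
#' @param target_fs Decimation target for signal-based measures (Hz).
#' @param max_samples Cap on the decimated series length; longer windows
#'   contribute their central segment (entropy estimates stabilise well
#'   before this length while the template search cost is quadratic).
#' @return Named numeric vector of length 26 (`NA` where undefined).
#' @export
extract_nonlinear <- function(x, rr, fs, target_fs = 125, max_samples = 500) {
  dec <- max(1L, floor(fs / target_fs))
  xs <- x[seq(1, length(x), by = dec)]
  if (length(xs) > max_samples) {
    # quadratic-cost estimators stabilise well before ~500 points; use the
    # central segment of that length
    lo <- (length(xs) - max_samples) %/% 2L
    xs <- xs[(lo + 1):(lo + max_samples)]
  }
  n26 <- length(.nonlin_names)
  out <- rep(NA_real_, n26)
  names(out) <- .nonlin_names

  ent <- function(fun, series, r) {
    if (length(series) < 20) return(NA_real_)
    tryCatch(fun(series, m = 2L, r = r), error = function(e) NA_real_)
  }
  out["sampen_rr_r15"] <- ent(sample_entropy, rr, 0.15)
  out["sampen_rr_r20"] <- ent(sample_entropy, rr, 0.20)
  out["sampen_rr_r25"] <- ent(sample_entropy, rr, 0.25)
  out["apen_rr_r15"] <- ent(approx_entropy, rr, 0.15)
  out["apen_rr_r20"] <- ent(approx_entropy, rr, 0.20)
  out["apen_rr_r25"] <- ent(approx_entropy, rr, 0.25)
  out["fuzzen_rr_r15"] <- ent(fuzzy_entropy, rr, 0.15)
  out["fuzzen_rr_r20"] <- ent(fuzzy_entropy, rr, 0.20)
  out["fuzzen_rr_r25"] <- ent(fuzzy_entropy, rr, 0.25)

  if (length(rr) >= 3) {
    d <- diff(rr)
    sd1 <- sqrt(stats::var(d) / 2)
    sd2v <- 2 * stats::var(rr) - stats::var(d) / 2
    sd2 <- sqrt(max(sd2v, 0))
    out["poincare_sd1"] <- sd1
    out["poincare_sd2"] <- sd2
    out["poincare_ratio"] <- if (sd2 > 1e-12) sd1 / sd2 else NA_real_
    out["poincare_area"] <- pi * sd1 * sd2
    out["shannon_entropy_rr"] <- .hist_entropy(rr, order = 1)
    out["renyi2_entropy_rr"] <- .hist_entropy(rr, order = 2)
  }

  if (length(xs) >= 40) {
    out["sampen_sig"] <- ent(sample_entropy, xs, 0.20)
    out["apen_sig"] <- ent(approx_entropy, xs, 0.20)
    out["fuzzen_sig"] <- ent(fuzzy_entropy, xs, 0.20)
    out["higuchi_fd"] <- .higuchi_fd(xs)
    out["katz_fd"] <- .katz_fd(xs)
    out["petrosian_fd"] <- .petrosian_fd(xs)
    hj <- .hjorth(xs)
    out["hjorth_mobility"] <- hj[1]
    out["hjorth_complexity"] <- hj[2]
    out["lz_complexity"] <- .lz_complexity(xs)
    out["zero_cross_rate"] <- mean(diff(sign(xs - stats::median(xs))) != 0)
  }
  out["dfa_alpha1"] <- .dfa_alpha1(if (length(rr) >= 20) rr else xs)
  out
}

# ---- assembly -------------------------------------------------------------

#' Extract the full 118-attribute vector for one record
#'
#' Runs fiducial detection on the configured lead, then the four family
#' extractors, concatenated in the frozen order time -> frequency ->
#' morphological -> nonlinear.
#'
#' @param record An `ecg_record`.
#' @param lead Lead used for all single-lead computations (default `"II"`).
#' @param fiducials Optional precomputed `fiducial_points`; detected when
#'   missing.
#' @return Named numeric vector of length 118 (`NA` for undefined entries).
#' @examples
#' rec <- generate_record(rhythm_spec("Normal"), seed = 1)
#' v <- extract_all(rec)
#' length(v)
#' @export
extract_all <- function(record, lead = "II", fiducials = NULL) {
  fid <- fiducials %||% find_fiducials(record, lead = lead)
  x <- record$signal[lead, ]
  fs <- record$fs
  dur <- length(x) / fs
  fail <- function(family, e) {
    stopf("feature family '%s' failed: %s", family, conditionMessage(e))
  }
  td <- tryCatch(extract_time_domain(fid, fs, duration_s = dur),
                 error = function(e) fail("time_domain", e))
  fd <- tryCatch(extract_frequency_domain(x, fs),
                 error = function(e) fail("frequency_domain", e))
  mg <- tryCatch(extract_morphological(x, fid, fs),
                 error = function(e) fail("morphological", e))
  rr <- diff(fid$r) / fs
  nl <- tryCatch(extract_nonlinear(x, rr, fs),
                 error = function(e) fail("nonlinear", e))
  v <- c(td, fd, mg, nl)
  v[!is.finite(v)] <- NA_real_
  v
}

#' Feature table for a dataset
#'
#' Applies [extract_all()] to each record and binds the results into a
#' tibble, one row per record.
#'
#' @param records List of `ecg_record`s.
#' @param lead Lead name.
#' @return Tibble: `record_id` plus the 118 catalog columns.
#' @export
extract_features <- function(records, lead = "II") {
  purrr::map_dfr(records, function(r) {
    v <- extract_all(r, lead = lead)
    tibble::as_tibble_row(c(list(record_id = r$record_id), as.list(v)))
  })
}

#' Impute undefined feature values with column medians
#'
#' The catalog's sentinel policy: `NA` entries (features undefined on a
#' record, e.g. entropies of too-short series) are replaced by the column
#' median computed on a reference (training) table.
#'
#' @param tbl Feature tibble (as from [extract_features()]).
#' @param reference Tibble supplying the medians; defaults to `tbl` itself.
#' @return Tibble with the same shape and no `NA` in numeric columns.
#' @export
impute_features <- function(tbl, reference = tbl) {
  num_cols <- names(tbl)[vapply(tbl, is.numeric, TRUE)]
  for (cl in num_cols) {
    med <- stats::median(reference[[cl]], na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    tbl[[cl]][!is.finite(tbl[[cl]])] <- med
  }
  tbl
}

#' Build the windowed feature matrix for one record
#'
#' Slides a window along the record and computes, per window, a signal
#' summary column (root-mean-square of the window, the raw-signal term of
#' the window representation) followed by the selected catalog features
#' recomputed on that window. Columns are z-scored with externally supplied
#' parameters so normalization can be fit on training data only.
#'
#' @param record An `ecg_record`.
#' @param selected_features Character vector of catalog names (nonempty).
#' @param window_length_s,stride_s Window geometry in seconds (defaults 2, 1).
#' @param zparams Optional list with `mean` and `sd` named vectors used to
#'   z-score columns; when `NULL` the matrix is returned unscaled.
#' @param lead Lead name.
#' @param fiducials Optional precomputed fiducials for the whole record.
#' @param record_fallback When `TRUE` (default), a feature that is undefined
#'   on a short window (e.g. RR statistics with fewer than 3 beats in the
#'   window, entropies of too-short series) takes the record-level value of
#'   that feature; local estimates are used wherever they exist. With
#'   `FALSE` such entries stay `NA` for downstream median imputation.
#' @param record_features Optional precomputed [extract_all()] vector for
#'   the record, used for the fallback (computed on demand when `NULL`).
#' @return A matrix (windows x (1 + k)) with attribute `zparams`; column 1
#'   is `signal_rms`.
#' @export
build_window_matrix <- function(record, selected_features,
                                window_length_s = 2, stride_s = 1,
                                zparams = NULL, lead = "II",
                                fiducials = NULL, record_fallback = TRUE,
                                record_features = NULL) {
  if (!length(selected_features)) stopf("`selected_features` must be nonempty")
  unknown <- setdiff(selected_features, feature_catalog()$name)
  if (length(unknown)) stopf("unknown features: %s", paste(unknown, collapse = ", "))
  x <- record$signal[lead, ]
  fs <- record$fs
  dur <- length(x) / fs
  if (window_length_s > dur) stopf("window longer than the record")
  fid <- fiducials %||% find_fiducials(record, lead = lead)

  wlen <- round(window_length_s * fs)
  step <- round(stride_s * fs)
  starts <- seq(1L, length(x) - wlen + 1L, by = step)

  catalog <- feature_catalog()
  fam <- catalog$category[match(selected_features, catalog$name)]
  need <- unique(fam)

  rows <- purrr::map(starts, function(s0) {
    idx <- s0:(s0 + wlen - 1L)
    xw <- x[idx]
    in_win <- fid$r >= idx[1] & fid$r <= idx[length(idx)]
    fid_w <- fid[in_win, ]
    vals <- stats::setNames(rep(NA_real_, length(selected_features)),
                            selected_features)
    if ("time_domain" %in% need && nrow(fid_w) >= 3) {
      td <- extract_time_domain(fid_w, fs, duration_s = window_length_s)
      vals[fam == "time_domain"] <- td[selected_features[fam == "time_domain"]]
    }
    if ("frequency_domain" %in% need && length(xw) >= fs) {
      fd <- extract_frequency_domain(xw, fs)
      vals[fam == "frequency_domain"] <-
        fd[selected_features[fam == "frequency_domain"]]
    }
    if ("morphological" %in% need) {
      fid_c <- dplyr::filter(fid_w, !is.na(.data$q), !is.na(.data$s))
      if (nrow(fid_c) >= 1) {
        mg <- extract_morphological(x, fid_w, fs)
        vals[fam == "morphological"] <-
          mg[selected_features[fam == "morphological"]]
      }
    }
    if ("nonlinear" %in% need) {
      rr_w <- diff(fid_w$r) / fs
      nl <- extract_nonlinear(xw, rr_w, fs)
      vals[fam == "nonlinear"] <- nl[selected_features[fam == "nonlinear"]]
    }
    c(signal_rms = sqrt(mean(xw^2)), vals)
  })
  M <- do.call(rbind, rows)
  M[!is.finite(M)] <- NA_real_

  if (record_fallback && anyNA(M)) {
    glob <- record_features %||% extract_all(record, lead = lead,
                                             fiducials = fid)
    for (cl in selected_features) {
      bad <- is.na(M[, cl])
      if (any(bad) && is.finite(glob[[cl]])) M[bad, cl] <- glob[[cl]]
    }
  }

  if (!is.null(zparams)) {
    mu <- zparams$mean[colnames(M)]
    sdv <- zparams$sd[colnames(M)]
    sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
    M <- sweep(sweep(M, 2, mu, "-"), 2, sdv, "/")
    attr(M, "zparams") <- zparams
  }
  attr(M, "window_length_s") <- window_length_s
  attr(M, "stride_s") <- stride_s
  M
}

#' Fit z-score parameters over a set of window matrices
#'
#' Computes per-column mean and SD pooled over all rows of the supplied
#' matrices (the training partition), plus the per-column median used to
#' impute remaining `NA` windows.
#'
#' @param mats List of unscaled window matrices.
#' @return List with named vectors `mean`, `sd`, `median`.
#' @export
fit_zparams <- function(mats) {
  all_rows <- do.call(rbind, mats)
  list(
    mean = apply(all_rows, 2, function(v) {
      m <- mean(v, na.rm = TRUE); if (is.finite(m)) m else 0
    }),
    sd = apply(all_rows, 2, function(v) {
      s <- stats::sd(v, na.rm = TRUE); if (is.finite(s) && s > 1e-12) s else 1
    }),
    median = apply(all_rows, 2, function(v) {
      m <- stats::median(v, na.rm = TRUE); if (is.finite(m)) m else 0
    })
  )
}

#' Apply z-scoring and imputation to a window matrix
#'
#' @param M Unscaled window matrix.
#' @param zparams Parameters from [fit_zparams()].
#' @return Scaled matrix with no `NA`s.
#' @export
apply_zparams <- function(M, zparams) {
  for (cl in colnames(M)) {
    v <- M[, cl]
    v[!is.finite(v)] <- zparams$median[[cl]] %||% 0
    M[, cl] <- (v - zparams$mean[[cl]]) / max(zparams$sd[[cl]], 1e-12)
  }
  M
}
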