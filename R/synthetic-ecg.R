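# Synthetic multi-label 12-lead ECG generator.
#
# Each heartbeat is a sum of five Gaussian bumps (P, Q, R, S, T) placed at
# physiologic offsets around the R peak, projected onto 12 leads through a
# fixed amplitude table, and repeated at RR intervals drawn from a rhythm
# specification. Class-specific morphology perturbations emulate the six
# rhythm classes: AF suppresses the P wave and inflates RR variability, PVC
# widens the QRS on a random subset of beats, PAC shortens the coupling
# interval before ectopic beats, LBBB/RBBB widen the QRS on every beat and
# flip its polarity on a class-specific subset of precordial/lateral leads.
# Noise is additive white Gaussian only: baseline wander and powerline
# artefacts are deliberately not simulated.

# Gaussian bump parameters of the archetypal beat, relative to the R peak.
# Offsets and widths in seconds, amplitudes in millivolts (lead II scale).
.beat_template <- function() {
  list(
    p = list(offset = -0.160, amp = 0.12, width = 0.025),
    q = list(offset = -0.035, amp = -0.15, width = 0.010),
    r = list(offset = 0.000, amp = 1.00, width = 0.012),
    s = list(offset = 0.035, amp = -0.20, width = 0.010),
    t = list(offset = 0.250, amp = 0.30, width = 0.050)
  )
}

.lead_names <- c("I", "II", "III", "aVR", "aVL", "aVF",
                 "V1", "V2", "V3", "V4", "V5", "V6")

# Fixed 12-entry projection: overall amplitude multiplier per lead.
# Lead II is the reference (multiplier 1) and is never polarity-flipped, so
# ground-truth R peaks are always local maxima of lead II.
.lead_projection <- c(0.60, 1.00, 0.50, -0.40, 0.30, 0.70,
                      -0.30, 0.45, 0.65, 0.90, 0.85, 0.70)

# Leads whose QRS polarity is flipped per bundle-branch-block class.
.bbb_flip_leads <- list(
  LBBB = c("V1", "V2", "V3"),
  RBBB = c("I", "V5", "V6")
)

#' Rhythm specification for the synthetic generator
#'
#' Bundles the class name, target heart rate, RR-interval variability and
#' per-wave morphology multipliers that define how beats of one rhythm class
#' are synthesised. Class defaults encode the distinguishing morphology:
#' `AF` has no P wave and strongly irregular RR intervals; `PVC` widens the
#' QRS (2x) and drops the P wave on a random quarter of beats; `PAC`
#' shortens the coupling interval before a quarter of beats; `LBBB`/`RBBB`
#' widen the QRS on every beat (1.8x / 1.6x) with lead-dependent polarity
#' reversal.
#'
#' @param class_name One of `ecg_classes()`.
#' @param heart_rate_bpm Mean heart rate in beats per minute, in `[30, 220]`.
#' @param rr_jitter Coefficient of variation of the RR intervals
#'   (dimensionless, `>= 0`).
#' @param morphology Optional named list overriding the class-default
#'   multipliers `p_amp`, `qrs_amp`, `qrs_width`, `t_amp`, `ectopic_fraction`.
#' @return An object of class `rhythm_spec`.
#' @examples
#' rhythm_spec("AF")
#' rhythm_spec("Normal", heart_rate_bpm = 60, rr_jitter = 0)
#' @export
rhythm_spec <- function(class_name,
                        heart_rate_bpm = NULL,
                        rr_jitter = NULL,
                        morphology = list()) {
  if (!is.character(class_name) || length(class_name) != 1L ||
      !class_name %in% ecg_classes()) {
    stopf("`class_name` must be one of: %s", paste(ecg_classes(), collapse = ", "))
  }
  defaults <- switch(class_name,
    Normal = list(hr = 75, jitter = 0.03,
                  morph = list(p_amp = 1, qrs_amp = 1, qrs_width = 1,
                               t_amp = 1, ectopic_fraction = 0)),
    AF = list(hr = 95, jitter = 0.18,
              morph = list(p_amp = 0, qrs_amp = 1, qrs_width = 1,
                           t_amp = 1, ectopic_fraction = 0)),
    PVC = list(hr = 75, jitter = 0.03,
               morph = list(p_amp = 1, qrs_amp = 1, qrs_width = 1,
                            t_amp = 1, ectopic_fraction = 0.25,
                            ectopic_qrs_width = 2.0, ectopic_qrs_amp = 1.3)),
    PAC = list(hr = 75, jitter = 0.03,
               morph = list(p_amp = 1, qrs_amp = 1, qrs_width = 1,
                            t_amp = 1, ectopic_fraction = 0.25,
                            ectopic_coupling = 0.65, ectopic_p_amp = 0.6)),
    LBBB = list(hr = 70, jitter = 0.03,
                morph = list(p_amp = 1, qrs_amp = 1, qrs_width = 1.8,
                             t_amp = 0.8, ectopic_fraction = 0)),
    RBBB = list(hr = 70, jitter = 0.03,
                morph = list(p_amp = 1, qrs_amp = 1, qrs_width = 1.6,
                             t_amp = 0.8, ectopic_fraction = 0))
  )
  hr <- heart_rate_bpm %||% defaults$hr
  jitter <- rr_jitter %||% defaults$jitter
  assert_scalar_num(hr, "heart_rate_bpm", 30, 220)
  assert_scalar_num(jitter, "rr_jitter", 0)
  morph <- utils::modifyList(defaults$morph, morphology)
  structure(
    list(class_name = class_name, heart_rate_bpm = hr,
         rr_jitter = jitter, morphology = morph),
    class = "rhythm_spec"
  )
}

#' @export
print.rhythm_spec <- function(x, ...) {
  cat(sprintf("<rhythm_spec> %s: %g bpm, RR jitter %g\n",
              x$class_name, x$heart_rate_bpm, x$rr_jitter))
  invisible(x)
}

# Draw RR intervals (seconds) for one spec until `duration_s` is covered.
.draw_rr <- function(spec, duration_s) {
  base <- 60 / spec$heart_rate_bpm
  n_max <- ceiling(duration_s / base * 2) + 8L
  rr <- base * pmax(0.4, 1 + spec$rr_jitter * stats::rnorm(n_max))
  rr
}

# Per-beat wave parameter table for one spec: ectopic beats get the spec's
# ectopic morphology, others the base morphology.
.beat_params <- function(spec, n_beats) {
  m <- spec$morphology
  ect <- rep(FALSE, n_beats)
  if ((m$ectopic_fraction %||% 0) > 0 && n_beats > 1) {
    k <- max(1L, round(m$ectopic_fraction * n_beats))
    ect[sample.int(n_beats, min(k, n_beats))] <- TRUE
  }
  lapply(seq_len(n_beats), function(i) {
    p <- list(
      p_amp = m$p_amp, qrs_amp = m$qrs_amp, qrs_width = m$qrs_width,
      t_amp = m$t_amp, coupling = 1, ectopic = ect[i]
    )
    if (ect[i] && spec$class_name == "PVC") {
      p$qrs_width <- m$ectopic_qrs_width
      p$qrs_amp <- m$ectopic_qrs_amp
      p$p_amp <- 0
      p$t_amp <- -m$t_amp # discordant T on ventricular ectopy
    }
    if (ect[i] && spec$class_name == "PAC") {
      p$coupling <- m$ectopic_coupling
      p$p_amp <- m$ectopic_p_amp
    }
    p
  })
}

#' Generate one synthetic multi-label 12-lead ECG record
#'
#' Builds a 12-lead record by repeating a five-Gaussian beat template at RR
#' intervals drawn per rhythm specification and adding white Gaussian noise.
#' When several specifications are supplied (a multi-label record), beats are
#' partitioned among them in alternating blocks of four, so each beat's
#' morphology is attributable to exactly one class.
#'
#' @param specs A `rhythm_spec` or list of them; the record's labels are the
#'   union of their class names.
#' @param duration_s Record duration in seconds, in `[6, 60]`.
#' @param fs Sampling frequency in Hz (default 500).
#' @param noise_sd Standard deviation of additive white Gaussian noise, mV.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   records.
#' @param record_id Record identifier string.
#' @return An `ecg_record`: list with `signal` (12 x samples matrix, mV, lead
#'   names as rownames), `fs`, `labels`, `beat_times` (ground-truth R-peak
#'   sample indices), `beat_class` (per-beat class name) and `record_id`.
#' @examples
#' rec <- generate_record(rhythm_spec("Normal", 60, rr_jitter = 0),
#'                        duration_s = 10, noise_sd = 0, seed = 1)
#' length(rec$beat_times)
#' @export
generate_record <- function(specs, duration_s = 10, fs = 500,
                            noise_sd = 0.02, seed = 1,
                            record_id = "synthetic") {
  if (inherits(specs, "rhythm_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "rhythm_spec"))) {
    stopf("`specs` must be one or more rhythm_spec objects")
  }
  assert_scalar_num(duration_s, "duration_s", 6, 60)
  assert_scalar_num(fs, "fs", 1e-9)
  assert_scalar_num(noise_sd, "noise_sd", 0)

  with_seed(seed, {
    n_samples <- round(duration_s * fs)
    tgrid <- (seq_len(n_samples) - 1) / fs
    template <- .beat_template()

    # Beat schedule: alternate blocks of 4 beats between specs; each beat's RR
    # comes from its spec. First R placed half a mean RR into the record.
    block <- 4L
    spec_of_beat <- integer(0)
    centers <- numeric(0)
    t_cur <- 0.5 * 60 / specs[[1]]$heart_rate_bpm
    k <- 0L
    while (t_cur < duration_s - 0.35) {
      s_idx <- (k %/% block) %% length(specs) + 1L
      spec <- specs[[s_idx]]
      centers <- c(centers, t_cur)
      spec_of_beat <- c(spec_of_beat, s_idx)
      base <- 60 / spec$heart_rate_bpm
      rr <- base * max(0.4, 1 + spec$rr_jitter * stats::rnorm(1))
      t_cur <- t_cur + rr
      k <- k + 1L
    }
    n_beats <- length(centers)
    if (n_beats < 2) stopf("duration too short for the requested heart rate")

    # Per-beat morphology; PAC coupling shortens the interval *before* the
    # ectopic beat, so shift that beat earlier.
    params <- vector("list", n_beats)
    for (s_idx in seq_along(specs)) {
      beats_s <- which(spec_of_beat == s_idx)
      params[beats_s] <- .beat_params(specs[[s_idx]], length(beats_s))
    }
    for (i in seq_len(n_beats)) {
      if (i > 1 && params[[i]]$coupling < 1) {
        gap <- centers[i] - centers[i - 1]
        centers[i] <- centers[i - 1] + gap * params[[i]]$coupling
      }
    }

    clean <- numeric(n_samples) # lead II reference waveform
    for (i in seq_len(n_beats)) {
      p <- params[[i]]
      for (w in names(template)) {
        tw <- template[[w]]
        amp <- tw$amp
        width <- tw$width
        offset <- tw$offset
        if (w == "p") amp <- amp * p$p_amp
        if (w %in% c("q", "r", "s")) {
          amp <- amp * p$qrs_amp
          width <- width * p$qrs_width
          offset <- offset * p$qrs_width
        }
        if (w == "t") amp <- amp * p$t_amp
        if (amp == 0) next
        tc <- centers[i] + offset
        idx <- which(tgrid > tc - 5 * width & tgrid < tc + 5 * width)
        clean[idx] <- clean[idx] + amp * exp(-((tgrid[idx] - tc)^2) / (2 * width^2))
      }
    }

    # Project onto 12 leads; flip QRS polarity on BBB-affected leads by
    # re-synthesising the QRS complex with reversed sign on those leads.
    signal <- outer(.lead_projection, clean)
    rownames(signal) <- .lead_names
    flip_classes <- intersect(names(.bbb_flip_leads),
                              vapply(specs, `[[`, "", "class_name"))
    for (cls in flip_classes) {
      leads <- match(.bbb_flip_leads[[cls]], .lead_names)
      beats_cls <- which(vapply(spec_of_beat, function(s)
        specs[[s]]$class_name == cls, TRUE))
      for (i in beats_cls) {
        p <- params[[i]]
        for (w in c("q", "r", "s")) {
          tw <- template[[w]]
          amp <- tw$amp * p$qrs_amp
          width <- tw$width * p$qrs_width
          tc <- centers[i] + tw$offset * p$qrs_width
          idx <- which(tgrid > tc - 5 * width & tgrid < tc + 5 * width)
          bump <- amp * exp(-((tgrid[idx] - tc)^2) / (2 * width^2))
          # subtract twice the projected bump: net effect is a sign flip
          signal[leads, idx] <- signal[leads, idx] -
            2 * .lead_projection[leads] %o% bump
        }
      }
    }

    if (noise_sd > 0) {
      signal <- signal + matrix(stats::rnorm(length(signal), sd = noise_sd),
                                nrow = nrow(signal))
    }

    beat_times <- round(centers * fs) + 1L
    labels <- unique(vapply(specs, `[[`, "", "class_name"))
    structure(
      list(signal = signal, fs = fs, labels = labels,
           beat_times = beat_times,
           beat_class = vapply(spec_of_beat, function(s)
             specs[[s]]$class_name, ""),
           record_id = record_id),
      class = "ecg_record"
    )
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d leads x %d samples @ %g Hz (%.1f s), labels {%s}, %d beats\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, paste(x$labels, collapse = ", "),
              length(x$beat_times)))
  invisible(x)
}

#' Generate a multi-label synthetic ECG dataset
#'
#' Draws each record's label set by independent Bernoulli sampling per class
#' (rejecting empty sets), then synthesises the record from the class-default
#' rhythm specifications of its labels. Default prevalences mirror a
#' multi-label arrhythmia cohort in which right bundle branch block and
#' atrial fibrillation dominate; because records are multi-label the
#' prevalences sum to more than 1.
#'
#' @param n_records Number of records (> 0).
#' @param prevalence Named numeric vector of per-class probabilities in
#'   `(0, 1]`; names must be a subset of `ecg_classes()`. Classes omitted are
#'   never drawn.
#' @param seed Integer seed.
#' @param duration_s,fs,noise_sd Passed to [generate_record()].
#' @return List of `ecg_record` objects.
#' @examples
#' ds <- generate_dataset(5, seed = 1, duration_s = 8)
#' purrr::map_chr(ds, ~ paste(.x$labels, collapse = "+"))
#' @export
generate_dataset <- function(n_records,
                             prevalence = c(Normal = 0.18, AF = 0.24,
                                            PVC = 0.14, PAC = 0.12,
                                            LBBB = 0.05, RBBB = 0.36),
                             seed = 1, duration_s = 10, fs = 500,
                             noise_sd = 0.02) {
  if (!is.numeric(n_records) || n_records < 1) stopf("`n_records` must be > 0")
  if (!length(prevalence)) stopf("`prevalence` must be a nonempty named vector")
  if (is.null(names(prevalence)) ||
      !all(names(prevalence) %in% ecg_classes())) {
    stopf("`prevalence` names must be classes among: %s",
          paste(ecg_classes(), collapse = ", "))
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    stopf("prevalences must lie in [0, 1]")
  }
  n_records <- as.integer(n_records)
  with_seed(seed, {
    classes <- names(prevalence)
    label_sets <- vector("list", n_records)
    for (i in seq_len(n_records)) {
      repeat {
        draw <- stats::runif(length(prevalence)) < prevalence
        if (any(draw)) break
      }
      label_sets[[i]] <- classes[draw]
    }
    sub_seeds <- sample.int(.Machine$integer.max %/% 2L, n_records)
    purrr::map(seq_len(n_records), function(i) {
      specs <- purrr::map(label_sets[[i]], rhythm_spec)
      generate_record(specs, duration_s = duration_s, fs = fs,
                      noise_sd = noise_sd, seed = sub_seeds[i],
                      record_id = sprintf("S%04d", i))
    })
  })
}

#' Summarise a dataset's label assignments as a tibble
#'
#' @param records List of `ecg_record`s.
#' @return Tibble with one row per record: `record_id`, `labels`
#'   (comma-separated) and one logical column per class.
#' @export
dataset_labels <- function(records) {
  classes <- ecg_classes()
  purrr::map_dfr(records, function(r) {
    row <- tibble::tibble(
      record_id = r$record_id,
      labels = paste(r$labels, collapse = ",")
    )
    for (cl in classes) row[[cl]] <- cl %in% r$labels
    row
  })
}

#' Binary label matrix of a dataset
#'
#' @param records List of `ecg_record`s.
#' @param classes Label columns to include (default all six).
#' @return n x m 0/1 matrix with class names as colnames.
#' @export
label_matrix <- function(records, classes = ecg_classes()) {
  Y <- vapply(records, function(r) as.integer(classes %in% r$labels),
              integer(length(classes)))
  Y <- t(Y)
  colnames(Y) <- classes
  rownames(Y) <- vapply(records, `[[`, "", "record_id")
  Y
}
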