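test_that("a 60 bpm jitter-free record has beats at exactly one-second spacing", {
  rec <- normal_record()
  expect_length(rec$beat_times, 10)
  expect_true(all(diff(rec$beat_times) == 500))
  expect_equal(dim(rec$signal), c(12, 5000))
  expect_identical(rec$labels, "Normal")
})

test_that("generation is bit-identical for identical arguments and seed", {
  a <- generate_record(rhythm_spec("Normal", 60, rr_jitter = 0),
                       duration_s = 10, noise_sd = 0, seed = 1)
  b <- normal_record()
  expect_identical(a$signal, b$signal)
  expect_identical(a$beat_times, b$beat_times)
  c2 <- generate_record(rhythm_spec("AF"), duration_s = 12, noise_sd = 0.03,
                        seed = 9)
  d2 <- generate_record(rhythm_spec("AF"), duration_s = 12, noise_sd = 0.03,
                        seed = 9)
  expect_identical(c2$signal, d2$signal)
})

test_that("multi-label AF+PVC records carry both labels and irregular rhythm", {
  rec <- generate_record(list(rhythm_spec("AF"), rhythm_spec("PVC")),
                         duration_s = 30, fs = 500, noise_sd = 0.02, seed = 7)
  expect_setequal(rec$labels, c("AF", "PVC"))
  cv <- function(r) stats::sd(diff(r$beat_times)) / mean(diff(r$beat_times))
  expect_gt(cv(rec), cv(normal_record()))
})

test_that("ground-truth R peaks sit on local maxima of lead II when noise-free", {
  for (cls in c("Normal", "AF", "PVC", "LBBB", "RBBB")) {
    rec <- generate_record(rhythm_spec(cls), duration_s = 10, noise_sd = 0,
                           seed = 3)
    x <- rec$signal["II", ]
    for (b in rec$beat_times) {
      win <- max(1, b - 3):min(length(x), b + 3)
      # the true peak of the R bump lies within +/- 3 samples of the index
      local <- (b - 25):(b + 25)
      expect_lte(abs(local[which.max(x[local])] - b), 3)
      expect_gt(max(x[win]), 0.5) # R wave dominates lead II
    }
  }
})

test_that("AF morphology removes the P bump and PVC widens the QRS", {
  af <- af_record()
  nrm <- normal_record()
  # amplitude around 160 ms before R (the P bump location); restrict to
  # beats with a preceding RR >= 0.6 s so the previous beat's T tail cannot
  # leak into the window
  p_height <- function(rec) {
    bt <- rec$beat_times
    ok <- c(FALSE, diff(bt) >= 300)
    stats::median(vapply(bt[ok], function(b) {
      max(rec$signal["II", (b - 85):(b - 75)])
    }, numeric(1)))
  }
  expect_lt(p_height(af), 0.1 * p_height(nrm))

  pvc <- pvc_record()
  # widen the Q/S search so the doubled-width ectopic QRS is not clipped
  wide <- utils::modifyList(delineation_windows(),
                            list(q_ms = 110, s_ms = 110))
  qrs_width <- function(rec) {
    fid <- delineate_waves(rec$signal["II", ], rec$fs, rec$beat_times,
                           windows = wide)
    (fid$s - fid$q) / rec$fs
  }
  w_pvc <- qrs_width(pvc)
  w_nrm <- stats::median(qrs_width(nrm))
  expect_gte(max(w_pvc, na.rm = TRUE), 1.5 * w_nrm)
})

test_that("argument validation rejects bad durations and classes", {
  expect_error(generate_record(rhythm_spec("Normal"), duration_s = 3),
               "duration_s")
  expect_error(generate_record(rhythm_spec("Normal"), duration_s = 90),
               "duration_s")
  expect_error(rhythm_spec("VF"), "class_name")
  expect_error(rhythm_spec("Normal", heart_rate_bpm = 300), "heart_rate_bpm")
  expect_error(generate_dataset(10, prevalence = numeric()), "nonempty")
})

test_that("dataset label draws honour the requested prevalences", {
  ds <- generate_dataset(100, prevalence = stats::setNames(rep(1, 6),
                                                           ecg_classes()),
                         seed = 3, duration_s = 6)
  expect_true(all(vapply(ds, function(r) length(r$labels) == 6, TRUE)))

  one <- generate_dataset(1, prevalence = c(Normal = 1), seed = 2,
                          duration_s = 6)
  expect_identical(one[[1]]$labels, "Normal")

  prev <- c(Normal = 0.18, AF = 0.24, PVC = 0.14, PAC = 0.12,
            LBBB = 0.05, RBBB = 0.36)
  ds2 <- generate_dataset(200, prevalence = prev, seed = 5, duration_s = 6)
  Y <- label_matrix(ds2)
  # empty label sets are rejected and redrawn, so the draw is conditioned
  # on at least one label: P(class | nonempty) = p / (1 - prod(1 - p))
  p_nonempty <- 1 - prod(1 - prev)
  for (cl in names(prev)) {
    p_cond <- prev[[cl]] / p_nonempty
    sd3 <- 3 * sqrt(p_cond * (1 - p_cond) / 200)
    expect_lt(abs(mean(Y[, cl]) - p_cond), sd3)
  }
})

test_that("record and dataset writers round-trip through text formats", {
  rec <- normal_record()
  dir <- withr::local_tempdir()
  write_ecg_wfdb(rec, dir)
  back <- read_ecg_wfdb(file.path(dir, paste0(rec$record_id, ".hea")),
                        labels = rec$labels)
  expect_equal(back$fs, rec$fs)
  expect_equal(unname(back$signal), unname(rec$signal), tolerance = 1e-6)
  expect_identical(rownames(back$signal), rownames(rec$signal))

  csv <- file.path(dir, "rec.csv")
  write_ecg_csv(rec, csv)
  back2 <- read_ecg_csv(csv, fs = rec$fs)
  expect_equal(unname(back2$signal), unname(rec$signal), tolerance = 1e-6)

  ds <- generate_dataset(3, seed = 8, duration_s = 6)
  ddir <- withr::local_tempdir()
  write_dataset(ds, ddir)
  back3 <- read_dataset(ddir)
  expect_length(back3, 3)
  expect_identical(back3[[2]]$labels, ds[[2]]$labels)
  expect_equal(unname(back3[[3]]$signal), unname(ds[[3]]$signal),
               tolerance = 1e-6)
})
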