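test_that("the catalog is locked at 118 uniquely named features, 27/35/30/26", {
  cat_tbl <- feature_catalog()
  expect_equal(nrow(cat_tbl), 118)
  expect_false(any(duplicated(cat_tbl$name)))
  counts <- table(cat_tbl$category)
  expect_equal(unname(counts[c("time_domain", "frequency_domain",
                               "morphological", "nonlinear")]),
               c(27, 35, 30, 26), ignore_attr = TRUE)
  expect_true(all(nzchar(cat_tbl$unit)))
})

test_that("time-domain statistics match hand computations", {
  v <- extract_time_domain(rep(1.0, 10))
  expect_equal(v[["rr_min"]], 1)
  expect_equal(v[["rr_max"]], 1)
  expect_equal(v[["rr_mean"]], 1)
  expect_equal(v[["rmssd"]], 0)
  expect_equal(v[["rr_sd"]], 0)

  v2 <- extract_time_domain(c(0.8, 1.0, 1.2))
  expect_equal(v2[["rmssd"]], 0.2) # sqrt((0.2^2 + 0.2^2) / 2)
  expect_equal(v2[["rr_diff_max_abs"]], 0.2)

  rec <- normal_record()
  fid <- find_fiducials(rec)
  v3 <- extract_time_domain(fid, rec$fs)
  expect_lt(abs(v3[["hr_median"]] - 60), 1)

  expect_error(extract_time_domain(fid[1:2, ], 500), "3 beats")
})

test_that("spectral features recognise pure tones, zero windows and flat spectra", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)[-1]
  v <- extract_frequency_domain(sin(2 * pi * 10 * t), fs)
  expect_lt(abs(v[["spectral_centroid"]] - 10), fs / length(t) + 1e-9)
  expect_lt(abs(v[["peak_freq"]] - 10), fs / length(t) + 1e-9)

  vz <- extract_frequency_domain(rep(0, 2 * fs), fs)
  expect_equal(unname(vz[paste0("bp_", 1:6)]), rep(0, 6))
  expect_equal(vz[["total_power"]], 0)
  expect_true(is.na(vz[["spectral_centroid"]]))

  # white noise: normalized band powers proportional to band widths
  widths <- diff(c(0.5, 4, 10, 15, 25, 40, fs / 2))
  expected <- widths / sum(widths)
  acc <- matrix(0, 30, 6)
  set.seed(99)
  for (s in 1:30) {
    vn <- extract_frequency_domain(rnorm(4 * fs), fs)
    acc[s, ] <- vn[paste0("bpn_", 1:6)]
  }
  expect_lt(max(abs(colMeans(acc) - expected)), 0.02)

  expect_error(extract_frequency_domain(rnorm(100), fs), "1 s")
})

test_that("morphological features recover the template's amplitudes", {
  rec <- normal_record()
  fid <- find_fiducials(rec)
  v <- extract_morphological(rec$signal["II", ], fid, rec$fs)
  expect_lt(abs(v[["r_amp_mean"]] - 1.0), 0.02)
  expect_lt(abs(v[["q_amp_mean"]] - (-0.15)), 0.02)
  expect_lt(abs(v[["s_amp_mean"]] - (-0.20)), 0.02)

  pvc <- pvc_record()
  v_pvc <- extract_morphological(pvc$signal["II", ], find_fiducials(pvc),
                                 pvc$fs)
  expect_gt(v_pvc[["qrs_width_mean"]], v[["qrs_width_mean"]])

  # with the T bump suppressed the ST segment is genuinely flat
  flat <- generate_record(rhythm_spec("Normal", 60, 0,
                                      morphology = list(t_amp = 0)),
                          duration_s = 10, noise_sd = 0, seed = 2)
  v_flat <- extract_morphological(flat$signal["II", ], find_fiducials(flat),
                                  flat$fs)
  expect_lt(abs(v_flat[["st_slope_mean"]]), 0.05)
})

test_that("entropies behave at the zero-complexity and noise limits", {
  expect_equal(sample_entropy(rep(3, 50)), 0)
  expect_equal(approx_entropy(rep(3, 50)), 0)

  set.seed(5)
  periodic <- rep(sin(2 * pi * (1:25) / 25), 8)
  noise <- rnorm(200)
  expect_lt(sample_entropy(periodic), sample_entropy(noise))
  expect_lt(fuzzy_entropy(periodic), fuzzy_entropy(noise))

  expect_error(sample_entropy(rnorm(10), m = 2), "too short")
})

test_that("sample entropy equals the brute-force template-counting oracle", {
  set.seed(8)
  for (i in 1:5) {
    # a noisy oscillation guarantees template matches at both lengths, so
    # the conditional probability (and both estimators) stay finite
    x <- sin(2 * pi * (1:30) / 10) + 0.15 * rnorm(30)
    r_abs <- 0.25 * sd(x)
    expect_equal(sample_entropy(x, m = 2, r = r_abs, r_relative = FALSE),
                 oracle_sampen(x, 2, r_abs), tolerance = 1e-10)
  }
})

test_that("extract_all returns the full deterministic catalog with sane scaling", {
  rec <- normal_record()
  v1 <- extract_all(rec)
  v2 <- extract_all(rec)
  expect_length(v1, 118)
  expect_identical(names(v1), feature_catalog()$name)
  expect_identical(v1, v2)

  scaled <- rec
  scaled$signal <- 2 * rec$signal
  v_s <- extract_all(scaled)
  # RR statistics are amplitude-invariant
  for (nm in c("rr_mean", "rr_sd", "rmssd", "hr_median")) {
    expect_equal(v_s[[nm]], v1[[nm]], tolerance = 1e-8)
  }
  # wave amplitudes scale linearly
  for (nm in c("r_amp_mean", "q_amp_mean", "s_amp_mean", "t_amp_mean")) {
    expect_equal(v_s[[nm]], 2 * v1[[nm]], tolerance = 1e-6)
  }
})

test_that("window matrices have the expected geometry and z-scoring", {
  # jitter and noise make windows differ, so z-scoring is non-degenerate
  rec <- generate_record(rhythm_spec("Normal"), duration_s = 10,
                         noise_sd = 0.02, seed = 31)
  sel <- c("rr_mean", "spectral_centroid", "r_amp_mean", "higuchi_fd")
  M <- build_window_matrix(rec, sel, window_length_s = 2, stride_s = 1)
  expect_equal(nrow(M), 9) # floor((10 - 2) / 1) + 1
  expect_equal(colnames(M), c("signal_rms", sel))

  zp <- fit_zparams(list(M))
  Mz <- apply_zparams(M, zp)
  filled <- colSums(is.finite(M)) == nrow(M) &
    apply(M, 2, sd, na.rm = TRUE) > 1e-12
  expect_gte(sum(filled), 3)
  expect_lt(max(abs(colMeans(Mz[, filled]))), 1e-9)
  expect_lt(max(abs(apply(Mz[, filled], 2, sd) - 1)), 1e-9)
  expect_false(any(!is.finite(Mz)))

  expect_error(build_window_matrix(rec, character()), "nonempty")
  expect_error(build_window_matrix(rec, "not_a_feature"), "unknown")
  expect_error(build_window_matrix(rec, sel, window_length_s = 99), "longer")
})

test_that("median imputation removes every non-finite entry", {
  tbl <- tibble::tibble(record_id = c("a", "b", "c"),
                        f1 = c(1, NA, 3), f2 = c(NA, NA, 5))
  out <- impute_features(tbl)
  expect_false(any(is.na(out$f1)))
  expect_equal(out$f1[2], 2) # median of 1, 3
  expect_equal(out$f2[1], 5)
})
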