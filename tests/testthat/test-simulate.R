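test_that("background EEG is reproducible, pink-ish, and weakly synchronized", {
  sc <- sim_config(duration_s = 60, seed = 1)
  b1 <- gen_background(sc, seed = 7)
  b2 <- gen_background(sc, seed = 7)
  expect_identical(b1$data, b2$data)
  expect_equal(colnames(b1$data), montage_10_20())

  # spectral slope of the 1/f background near the configured exponent
  x <- b1$data[, "Cz"]
  sp <- spec.pgram(ts(x, frequency = sc$fs), plot = FALSE, spans = 15)
  band <- sp$freq >= 1 & sp$freq <= 40
  fit <- lm(log(sp$spec[band]) ~ log(sp$freq[band]))
  expect_lt(abs(-coef(fit)[2] - sc$pink_exponent), 0.5)

  # independent channels: mean pairwise gamma over 1-s windows well below 0.5
  rec <- gen_background(sim_config(duration_s = 30, seed = 1), seed = 8)
  ph <- wavelet_phases(rec)
  tt <- (seq_len(nrow(ph)) - 1) / rec$fs
  g <- vapply(0:28, function(s) {
    idx <- tt >= s & tt < s + 1
    global_gamma(sync_matrix(ph[idx, , drop = FALSE]))
  }, numeric(1))
  expect_lt(mean(g), 0.5)
})

test_that("spike-and-wave segments are rhythmic and phase-locked", {
  sc <- sim_config(seed = 2)
  seg <- gen_swd(10, sc, target_rms = 100, seed = 3)
  expect_equal(dim(seg), c(2500, 19))
  expect_equal(sqrt(mean(seg^2)), 100, tolerance = 1e-9)
  # dominant spectral peak at the SWD repetition rate (3 Hz)
  sp <- Mod(fft(seg[, "Cz"]))[2:1250]
  f <- (1:1249) * sc$fs / 2500
  expect_lt(abs(f[which.max(sp)] - sc$swd_rate_hz), 0.2)
  # zero jitter and zero gain spread -> identical channels
  sc0 <- sim_config(swd_jitter_rad = 0, channel_gain_sd = 0, seed = 2)
  seg0 <- gen_swd(4, sc0, target_rms = 50, seed = 4)
  expect_equal(max(abs(seg0 - seg0[, 1])), 0)
  # near-perfect phase locking at the analysis frequency for zero jitter
  rec <- eeg_recording(seg0, sc$fs)
  ph <- wavelet_phases(rec)
  g <- global_gamma(sync_matrix(ph[500:750, , drop = FALSE]))
  expect_gt(g, 0.9)
})

test_that("generated recordings honour the seizure schedule contract", {
  sc <- sim_config(duration_s = 200, n_seizures = 3, seed = 11,
                   min_gap_s = 10)
  out <- gen_recording(sc, "S99", seed = 11)
  ann <- out$annotations
  expect_equal(nrow(ann), 3)
  expect_true(all(ann$onset_s >= 30))
  expect_true(all(ann$offset_s <= 200))
  o <- order(ann$onset_s)
  expect_true(all(ann$onset_s[o][-1] - ann$offset_s[o][-3] >= sc$min_gap_s))
  durs <- ann$offset_s - ann$onset_s
  expect_true(all(durs >= sc$seizure_min_s & durs <= sc$seizure_max_s))
  # zero seizures -> empty annotation set
  out0 <- gen_recording(sim_config(duration_s = 100, n_seizures = 0,
                                   seed = 3), "S98", seed = 3)
  expect_equal(nrow(out0$annotations), 0)
  # fixed durations sum as configured
  scf <- sim_config(duration_s = 300, n_seizures = 6, seizure_min_s = 10.5,
                    seizure_max_s = 10.5, seizure_mode_s = 10.5, seed = 5)
  outf <- gen_recording(scf, "S97", seed = 5)
  expect_equal(sum(outf$annotations$offset_s - outf$annotations$onset_s), 63)
  # too many seizures for the duration -> error
  expect_error(gen_recording(sim_config(duration_s = 100, n_seizures = 8,
                                        seed = 1), seed = 1), "fit")
})

test_that("implanted fragmentation gaps lie strictly inside seizures", {
  sc <- sim_config(duration_s = 250, n_seizures = 3, frag_fraction = 0.3,
                   seizure_min_s = 12, seizure_max_s = 18,
                   seizure_mode_s = 15, seed = 21, min_gap_s = 10)
  out <- gen_recording(sc, "F1", seed = 21)
  expect_equal(nrow(out$gaps), 3)
  for (i in seq_len(nrow(out$gaps))) {
    g <- out$gaps[i, ]
    a <- out$annotations[out$annotations$onset_s < g$onset_s &
                           out$annotations$offset_s > g$offset_s, ]
    expect_equal(nrow(a), 1)
    frac <- (g$offset_s - g$onset_s) / (a$offset_s - a$onset_s)
    expect_equal(frac, 0.3, tolerance = 1e-6)
  }
})

test_that("cohorts are reproducible with distinct per-subject schedules", {
  sc <- sim_config(n_subjects = 3, duration_s = 120, n_seizures = 2,
                   seed = 33)
  c1 <- gen_cohort(sc)
  c2 <- gen_cohort(sc)
  expect_identical(lapply(c1, function(s) s$recording$data),
                   lapply(c2, function(s) s$recording$data))
  expect_equal(length(c1), 3)
  ons <- lapply(c1, function(s) s$annotations$onset_s)
  expect_false(identical(ons[[1]], ons[[2]]))
  expect_error(gen_cohort(sim_config(n_subjects = 1)), "two subjects")
})

test_that("amplitude normalization cancels the subject amplitude scale", {
  # subjects spanning a 3x amplitude range keep ictal Am near the SWD gain
  cfg <- run_config(seed = 42)
  cf <- small_cohort_features()
  f <- cf$features[cf$features$taxonomy == 4L, ]
  med <- tapply(f$amplitude_norm, f$subject_id, median)
  expect_true(all(med > 2.5 & med < 6))
  expect_lt(max(med) / min(med), 1.5)
})

test_that("ictal and interictal windows separate in the feature plane", {
  cf <- small_cohort_features()
  f <- cf$features
  gap <- mean(f$gamma_mean[f$taxonomy %in% 3:5]) -
    mean(f$gamma_mean[f$taxonomy == 0])
  expect_gt(gap, 0.2)
})

test_that("unit SWD gain collapses the synchronization contrast", {
  sc <- sim_config(duration_s = 120, n_seizures = 3, swd_gain = 1,
                   min_gap_s = 10, seed = 55)
  out <- gen_recording(sc, "L1", seed = 55)
  f <- segment_features(out$recording, out$annotations, run_config(seed = 55))
  ict <- f$gamma_mean[f$taxonomy %in% 3:5]
  int <- f$gamma_mean[f$taxonomy == 0]
  # distributions overlap: the weak-discharge ictal range reaches into the
  # interictal bulk, so synchronization alone cannot separate the classes
  expect_gt(mean(int > min(ict)), 0.05)
})
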