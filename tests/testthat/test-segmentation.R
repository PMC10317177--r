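test_that("sliding windows cover the recording at half-second steps", {
  w <- segment_stream(10)
  expect_equal(nrow(w), 19)             # 2*10 - 1
  expect_equal(w$start, seq(0, 9, by = 0.5))
  expect_equal(w$end - w$start, rep(1, 19))
  expect_equal(nrow(segment_stream(1)), 1)
  expect_equal(nrow(segment_stream(0.9)), 0)
  # consecutive windows overlap by exactly half a window
  expect_equal(w$end[-19] - w$start[-1], rep(0.5, 18))
  for (d in c(5, 17, 120)) expect_equal(nrow(segment_stream(d)), 2 * d - 1)
})

test_that("taxonomy codes follow the onset/embedded/offset geometry", {
  w <- segment_stream(30)
  ann <- annotation_set("P1", 10.25, 10.0)   # seizure [10.25, 20.25)
  lab <- label_segments(w, ann)
  code_at <- function(start) lab$taxonomy[abs(lab$start - start) < 1e-9]
  expect_equal(code_at(9.5), 1L)
  expect_equal(code_at(10.0), 2L)
  expect_equal(code_at(10.5), 3L)
  expect_equal(code_at(14.0), 4L)
  expect_equal(code_at(19.0), 5L)
  expect_equal(code_at(19.5), 6L)
  expect_equal(code_at(20.0), 7L)
  expect_equal(code_at(9.0), 0L)
  expect_equal(code_at(20.5), 0L)
  expect_identical(lab$label, ifelse(lab$taxonomy != 0, "ictal", "interictal"))
})

test_that("grid-aligned onsets drop the second partial window", {
  w <- segment_stream(30)
  lab <- label_segments(w, annotation_set("P1", 10.0, 10.0))  # [10, 20)
  code_at <- function(start) lab$taxonomy[abs(lab$start - start) < 1e-9]
  # [9.5,10.5) is the only leading partial; [10,11) is fully embedded
  expect_equal(code_at(9.5), 1L)
  expect_equal(code_at(10.0), 3L)
  expect_false(any(lab$taxonomy == 2L))
  # [19.5, 20.5) is the single trailing partial -> 7; [19, 20) last embedded
  expect_equal(code_at(19.0), 5L)
  expect_equal(code_at(19.5), 7L)
  expect_false(any(lab$taxonomy == 6L))
  # no annotations -> all zero
  expect_true(all(label_segments(w, NULL)$taxonomy == 0L))
})

test_that("sub-window seizures get only partial codes", {
  w <- segment_stream(30)
  lab <- label_segments(w, annotation_set("P1", 10.3, 0.9))  # [10.3, 11.2)
  got <- lab$taxonomy[lab$taxonomy != 0]
  expect_equal(got, c(1L, 2L, 6L, 7L))
  expect_false(any(lab$taxonomy %in% 3:5))
})

test_that("binary label is the indicator of nonzero taxonomy", {
  set.seed(8)
  w <- segment_stream(120)
  for (i in 1:20) {
    on <- 25 + cumsum(runif(3, 8, 25))
    durs <- runif(3, 0.4, 6)
    ann <- annotation_set("X", on, durs)
    lab <- label_segments(w, ann)
    expect_identical(lab$label == "ictal", lab$taxonomy != 0L)
  }
})

test_that("amplitude reference uses the first seizure-free 30 s", {
  fs <- 100
  ch <- montage_10_20()
  x <- matrix(10, fs * 120, 19, dimnames = list(NULL, ch))
  rec <- eeg_recording(x, fs, subject_id = "A")
  expect_equal(reference_amplitude(rec)$A_ref, 10)
  # channel groups with distinct means average sample-wise
  x2 <- x; x2[, 1:10] <- 8; x2[, 11:19] <- 12
  ref <- reference_amplitude(eeg_recording(x2, fs, subject_id = "A"))
  expect_equal(ref$A_ref, mean(c(rep(8, 10), rep(12, 9))))
  # seizure in the first 30 s pushes the reference window later
  ann <- annotation_set("A", 5, 10)
  ref2 <- reference_amplitude(rec, ann)
  expect_equal(ref2$window, c(15, 45))
  # no seizure-free stretch -> error
  ann3 <- annotation_set("A", c(5, 60), c(40, 59))
  expect_error(reference_amplitude(rec, ann3), "no seizure-free")
  short <- eeg_recording(x[1:(20 * fs), ], fs)
  expect_error(reference_amplitude(short), "shorter")
})

test_that("window features combine global gamma and normalized amplitude", {
  fs <- 250
  ch <- montage_10_20()
  t <- (0:(fs * 40 - 1)) / fs
  base <- cos(2 * pi * 12 * t)
  x <- matrix(rep(base, 19), ncol = 19, dimnames = list(NULL, ch))
  # window [35, 36) has 4x the amplitude of the reference segment
  x[t >= 35 & t < 36, ] <- 4 * x[t >= 35 & t < 36, ]
  rec <- eeg_recording(x, fs, subject_id = "W")
  phases <- wavelet_phases(rec)
  A_ref <- reference_amplitude(rec)$A_ref
  f <- window_features(c(35, 36), phases, rec, "S19", A_ref)
  expect_equal(unname(f["gamma_mean"]), 1)       # identical channels
  expect_equal(unname(f["amplitude_norm"]), 4, tolerance = 1e-6)
  expect_error(window_features(c(0, 1), phases, rec, "S19", A_ref = 0),
               "A_ref")
})

test_that("per-recording feature table matches per-window recomputation", {
  s <- small_cohort()[[2]]
  cfg <- run_config(seed = 42)
  f <- segment_features(s$recording, s$annotations, cfg)
  expect_equal(nrow(f), 2 * 300 - 1)
  expect_true(all(f$gamma_mean >= 0 & f$gamma_mean <= 1))
  expect_true(all(f$amplitude_norm > 0))
  phases <- wavelet_phases(s$recording, cfg$fc, cfg$fa)
  A_ref <- reference_amplitude(s$recording, s$annotations)$A_ref
  for (i in c(1, 57, 400)) {
    wf <- window_features(c(f$start[i], f$end[i]), phases, s$recording,
                          "S19", A_ref)
    expect_equal(f$gamma_mean[i], unname(wf["gamma_mean"]), tolerance = 1e-12)
    expect_equal(f$amplitude_norm[i], unname(wf["amplitude_norm"]),
                 tolerance = 1e-12)
  }
  # gamma_mean equals the enumeration oracle on a sample window
  tt <- (seq_len(nrow(phases)) - 1) / s$recording$fs
  idx <- tt >= f$start[57] & tt < f$end[57]
  G <- sync_matrix(phases[idx, , drop = FALSE])
  expect_equal(f$gamma_mean[57], oracle_global_gamma(G))
})

test_that("taxonomy-ordered group synchronization has the ictal plateau", {
  cf <- small_cohort_features()
  prof <- tapply(cf$features$gamma_mean, cf$features$taxonomy, mean)
  expect_true(all(c("0", "3", "4", "5") %in% names(prof)))
  expect_equal(names(which.min(prof[c("0", "3", "4")])), "0")
  expect_gt(min(prof[c("3", "4")]), prof[["0"]])
  expect_equal(names(prof)[which.max(prof)] %in% c("3", "4", "5"), TRUE)
})
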