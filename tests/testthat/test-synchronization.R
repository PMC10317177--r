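test_that("gamma calibration: locked phases give 1, a uniform grid gives 0", {
  expect_equal(pairwise_gamma(rep(pi / 3, 250), rep(0, 250)), 1)
  set.seed(1)
  base <- runif(250, -pi, pi)
  expect_equal(pairwise_gamma(base + 0.7, base), 1)
  # uniform full-cycle grid of phase differences
  N <- 250
  expect_equal(pairwise_gamma(2 * pi * (0:(N - 1)) / N, rep(0, N)), 0,
               tolerance = 1e-12)
  expect_error(pairwise_gamma(rep(NA_real_, 10), rep(0, 10)), "no valid")
  expect_error(pairwise_gamma(1:3, 1:4), "equal length")
})

test_that("gamma stays in [0,1] and ignores common phase offsets", {
  set.seed(2)
  for (i in 1:200) {
    a <- runif(50, -pi, pi); b <- runif(50, -pi, pi)
    g <- pairwise_gamma(a, b)
    expect_gte(g, 0); expect_lte(g, 1)
    expect_equal(pairwise_gamma(a + 1.1, b + 1.1), g, tolerance = 1e-12)
  }
})

test_that("white-noise gamma matches the Monte-Carlo oracle distribution", {
  # Oracle: direct-convolution implementation (helper-oracles.R style),
  # 1000 independent 1-s pairs at 250 Hz, (fc, fa) = (1, 12), computed once:
  # mean 0.366594, se 0.005777.
  oracle_mean <- 0.366594
  oracle_se <- 0.005777
  fs <- 250
  g <- numeric(1000)
  set.seed(90210)
  for (i in seq_along(g)) {
    x1 <- rnorm(fs); x2 <- rnorm(fs)
    p1 <- phase_series(cwt_morlet(x1, fs, 1, 12))
    p2 <- phase_series(cwt_morlet(x2, fs, 1, 12))
    g[i] <- pairwise_gamma(p1, p2)
  }
  se <- sqrt(oracle_se^2 + var(g) / length(g))
  expect_lt(abs(mean(g) - oracle_mean), 3 * se)
})

test_that("gamma of noisy locked sinusoids decays with noise amplitude", {
  fs <- 250
  t <- (0:(fs - 1)) / fs
  base <- cos(2 * pi * 12 * t)
  mean_g <- function(noise_amp) {
    mean(replicate(200, {
      x1 <- base + noise_amp * rnorm(fs)
      x2 <- base + noise_amp * rnorm(fs)
      pairwise_gamma(phase_series(cwt_morlet(x1, fs, 1, 12)),
                     phase_series(cwt_morlet(x2, fs, 1, 12)))
    }))
  }
  set.seed(31)
  g <- vapply(c(0.2, 1, 4), mean_g, numeric(1))
  expect_true(all(diff(g) < 0))
  expect_gt(g[1], 0.9)
})

test_that("sync matrix is symmetric, unit-diagonal, and subset-aware", {
  set.seed(4)
  fs <- 250
  P <- matrix(runif(fs * 6, -pi, pi), ncol = 6,
              dimnames = list(NULL, channel_subset("S6")))
  G <- sync_matrix(P)
  expect_equal(G, t(G))
  expect_equal(diag(G), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(G >= 0 & G <= 1))
  # identical phases on all channels -> all entries 1
  P1 <- matrix(rep(runif(fs, -pi, pi), 4), ncol = 4,
               dimnames = list(NULL, channel_subset("S4")))
  expect_true(all(sync_matrix(P1) == 1))
  # S19 has 171 unordered pairs
  P19 <- matrix(runif(100 * 19, -pi, pi), ncol = 19,
                dimnames = list(NULL, montage_10_20()))
  expect_equal(sum(upper.tri(sync_matrix(P19))), 171)
  expect_error(sync_matrix(P, channels = c("Fp1", "Nope")), "missing channel")
  # window selection uses half-open sample times
  expect_error(sync_matrix(P, fs = fs, window = c(10, 11)), "no samples")
})

test_that("global and channel indices agree with enumeration oracles", {
  set.seed(5)
  for (name in c("S4", "S6", "S12", "S19")) {
    ch <- channel_subset(name)
    n <- length(ch)
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(ch, ch)
    expect_equal(global_gamma(m), oracle_global_gamma(m))
    for (k in c(1, n)) {
      expect_equal(channel_gamma(m, k), oracle_channel_gamma(m, k))
      expect_equal(channel_gamma(m, ch[k]), oracle_channel_gamma(m, k))
    }
    # mean over channels of the channel index equals the global index
    expect_equal(mean(vapply(1:n, function(k) channel_gamma(m, k),
                             numeric(1))),
                 global_gamma(m))
  }
  m2 <- matrix(0.7, 4, 4); diag(m2) <- 1
  expect_equal(channel_gamma(m2, 2), 0.7)
  expect_equal(global_gamma(m2), 0.7)
  expect_error(channel_gamma(m2, 9), "out of range")
})

test_that("grid search maximizes the ictal-interictal contrast objective", {
  s <- small_cohort()[[1]]
  cfg <- run_config(seed = 42)
  fc_grid <- c(0.8, 1.0); fa_grid <- c(6, 12)
  gs <- grid_search(s$recording, s$annotations, fc_grid, fa_grid, cfg)

  # exhaustive scripted evaluation of the same objective
  w <- label_segments(segment_stream(duration_s(s$recording)),
                      s$annotations, s$recording$subject_id)
  ref <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ph <- wavelet_phases(s$recording, fc_grid[i], fa_grid[j])
    tt <- (seq_len(nrow(ph)) - 1) / s$recording$fs
    g <- vapply(seq_len(nrow(w)), function(m) {
      idx <- which(tt >= w$start[m] & tt < w$end[m])
      global_gamma(sync_matrix(ph[idx, , drop = FALSE]))
    }, numeric(1))
    ref[i, j] <- 100 * (mean(g[w$label == "ictal"]) -
                          mean(g[w$label == "interictal"])) /
      mean(g[w$label == "interictal"])
  }
  expect_equal(unname(gs$objective), ref, tolerance = 1e-10)
  best_idx <- which(ref == max(ref), arr.ind = TRUE)[1, ]
  expect_equal(unname(gs$best),
               c(fc_grid[best_idx[1]], fa_grid[best_idx[2]]))
  # the 12-Hz band separates 3-Hz spike-and-wave seizures better than 6 Hz
  expect_gt(gs$objective["1", "12"], 0)

  interictal_only <- annotation_set(s$recording$subject_id, 1e5, 1)
  expect_error(grid_search(s$recording, interictal_only, 1, 12, cfg),
               "both ictal and interictal")
})
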