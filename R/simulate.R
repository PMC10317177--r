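#' Synthetic EEG simulation settings
#'
#' Parameters of the synthetic 19-channel spike-and-wave EEG generator used
#' to validate every pipeline stage without clinical data.  Defaults encode
#' the phenomenology of childhood/juvenile absence epilepsy EEG: 250-Hz
#' sampling, 15-min recordings, pink-noise background with a narrowband
#' alpha rhythm (stronger occipitally), generalized spike-and-wave
#' discharges at 3 Hz with amplitude 4x the background RMS and small
#' cross-channel phase jitter, six seizures per recording with durations
#' drawn from a triangular distribution on 3-20 s with mode 10 s (matching
#' the clinical min/max/median), none earlier than 30 s into the recording,
#' plus occasional short (< 2 s) interictal epileptiform bursts and frontal
#' blink artifacts.
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param fs Sampling frequency in Hz.
#' @param duration_s Recording duration per subject in seconds.
#' @param bg_rms_uv Background RMS amplitude in microvolts.
#' @param subject_scale_range Per-subject multiplicative amplitude scale is
#'   drawn uniformly from this range (children's EEG amplitude varies
#'   severalfold with age and electrode impedance).
#' @param pink_exponent Background `1/f^beta` spectral exponent.
#' @param alpha_freq,alpha_bw,alpha_rms_uv Alpha rhythm center frequency,
#'   bandwidth (Hz) and RMS amplitude; modelled as independent narrowband
#'   noise per channel.
#' @param alpha_occipital_gain Extra alpha gain on O1/O2.
#' @param channel_gain_sd SD of per-channel gain spread around 1.
#' @param swd_rate_hz Spike-and-wave repetition rate in Hz (2.5-5.5).
#' @param swd_gain Seizure amplitude as a multiple of background RMS.
#' @param swd_spike_sigma_s Spike width (Gaussian-derivative sigma) in s.
#' @param swd_jitter_rad SD of the per-channel phase jitter of the shared
#'   discharge, in radians of the SWD cycle.
#' @param n_seizures Seizures per recording.
#' @param seizure_min_s,seizure_max_s,seizure_mode_s Triangular duration
#'   distribution parameters in seconds.
#' @param min_gap_s Minimum interictal gap between seizures in seconds.
#' @param frag_fraction Fraction of each seizure replaced by a
#'   fragmentation gap (0 disables fragmentation).
#' @param frag_mode How the ictal rhythm is interrupted inside a gap:
#'   `"cessation"` (discharge replaced by background), `"spike_loss"`
#'   (spikes vanish, the slow delta wave persists) or `"desync"` (the
#'   discharge continues but cross-channel phase locking is destroyed).
#' @param burst_count Expected number of short interictal epileptiform
#'   bursts per recording (Poisson).
#' @param burst_min_s,burst_max_s Burst duration range in seconds.
#' @param burst_gain Burst amplitude as a multiple of background RMS.
#' @param blink_count Expected number of frontal blink artifacts (Poisson).
#' @param seed Master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10L, fs = 250, duration_s = 900,
                       bg_rms_uv = 20, subject_scale_range = c(0.6, 1.8),
                       pink_exponent = 1,
                       alpha_freq = 10, alpha_bw = 1, alpha_rms_uv = 8,
                       alpha_occipital_gain = 2, channel_gain_sd = 0.1,
                       swd_rate_hz = 3, swd_gain = 4,
                       swd_spike_sigma_s = 0.012, swd_jitter_rad = 0.3,
                       n_seizures = 6L,
                       seizure_min_s = 3, seizure_max_s = 20,
                       seizure_mode_s = 10, min_gap_s = 15,
                       frag_fraction = 0,
                       frag_mode = c("cessation", "spike_loss", "desync"),
                       burst_count = 2, burst_min_s = 0.3, burst_max_s = 1,
                       burst_gain = 3, blink_count = 8, seed = 1L) {
  stopifnot(fs > 0, duration_s > 0, swd_rate_hz >= 2, swd_rate_hz <= 6,
            swd_gain > 0, n_seizures >= 0,
            seizure_min_s <= seizure_mode_s,
            seizure_mode_s <= seizure_max_s,
            frag_fraction >= 0, frag_fraction < 1)
  frag_mode <- match.arg(frag_mode)
  structure(as.list(environment()), class = "sim_config")
}

# triangular(min, max, mode) sampler via inverse CDF
rtriangular <- function(n, lo, hi, mode) {
  if (hi <= lo) return(rep(lo, n))
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

# n samples of unit-variance noise with 1/f^exponent power spectrum
colored_noise <- function(n, exponent, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, pmin(1:(n - 1), n - 1:(n - 1))) * fs / n
  g <- c(0, f[-1]^(-exponent / 2))
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

# narrowband (Gaussian passband) unit-variance noise around f0
narrowband_noise <- function(n, f0, bw, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, pmin(1:(n - 1), n - 1:(n - 1))) * fs / n
  g <- exp(-(f - f0)^2 / (2 * bw^2))
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate interictal background EEG
#'
#' Per-channel independent pink noise plus narrowband alpha-rhythm noise
#' with occipital emphasis.  Channels are statistically independent, so
#' interictal phase synchronization at the analysis frequency stays low.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of samples (default `duration_s * fs`).
#' @param scale Multiplicative amplitude scale (per-subject factor).
#' @param seed Seed, or `NULL` to use the current RNG state.
#' @return An [eeg_recording()] with the 19-channel 10-20 montage.
#' @export
gen_background <- function(config = sim_config(),
                           n_samples = round(config$duration_s * config$fs),
                           scale = 1, seed = NULL) {
  with_seed(seed, {
    ch <- montage_10_20()
    data <- matrix(0, n_samples, length(ch))
    gains <- 1 + stats::rnorm(length(ch), 0, config$channel_gain_sd)
    gains <- pmax(gains, 0.5)
    for (j in seq_along(ch)) {
      pink <- colored_noise(n_samples, config$pink_exponent, config$fs) *
        config$bg_rms_uv
      ag <- config$alpha_rms_uv *
        if (ch[j] %in% c("O1", "O2")) config$alpha_occipital_gain else 1
      alpha <- narrowband_noise(n_samples, config$alpha_freq,
                                config$alpha_bw, config$fs) * ag
      data[, j] <- scale * gains[j] * (pink + alpha)
    }
    colnames(data) <- ch
    eeg_recording(data, config$fs)
  })
}

# one spike-and-wave cycle of duration 1/rate: sharp Gaussian-derivative
# spike followed by a slow half-sine wave
swd_cycle <- function(rate, fs, spike_sigma, spikes = TRUE) {
  period <- 1 / rate
  t <- seq(0, period - 1 / fs, by = 1 / fs)
  t_sp <- 0.12 * period
  spike <- -(t - t_sp) / spike_sigma * exp(-(t - t_sp)^2 / (2 * spike_sigma^2))
  spike <- spike / max(abs(spike))
  wave <- numeric(length(t))
  in_wave <- t >= 0.25 * period
  wave[in_wave] <- sin(pi * (t[in_wave] - 0.25 * period) / (0.75 * period))
  if (spikes) spike + 0.6 * wave else 0.6 * wave
}

#' Generate a generalized spike-and-wave discharge segment
#'
#' A shared spike-and-wave waveform (repetition rate `swd_rate_hz`) is
#' broadcast to all 19 channels with per-channel gain spread and a small
#' per-channel time shift corresponding to the configured phase jitter of
#' the SWD cycle, then scaled so the mean channel RMS equals
#' `target_rms` (normally `swd_gain` times the background RMS).
#'
#' @param duration_s Segment duration in seconds.
#' @param config A [sim_config()].
#' @param target_rms Target mean channel RMS in microvolts.
#' @param jitter_rad Per-channel phase jitter SD in radians (default from
#'   `config`); large values desynchronize the channels.
#' @param spikes Include the epileptic spikes (`FALSE` leaves only the slow
#'   delta wave).
#' @param uniform_jitter Draw the per-channel shifts uniformly over the
#'   whole cycle instead of `N(0, jitter)` (used by the `"desync"`
#'   fragmentation mode).
#' @param seed Seed, or `NULL`.
#' @return Numeric matrix (samples x 19 channels) in microvolts.
#' @export
gen_swd <- function(duration_s, config = sim_config(), target_rms,
                    jitter_rad = config$swd_jitter_rad, spikes = TRUE,
                    uniform_jitter = FALSE, seed = NULL) {
  with_seed(seed, {
    fs <- config$fs
    rate <- config$swd_rate_hz
    n <- round(duration_s * fs)
    cyc <- swd_cycle(rate, fs, config$swd_spike_sigma_s, spikes)
    base <- rep_len(cyc, n + 2 * length(cyc))
    ch <- montage_10_20()
    theta <- if (uniform_jitter) stats::runif(length(ch), -pi, pi)
    else stats::rnorm(length(ch), 0, jitter_rad)
    shift <- round(theta / (2 * pi * rate) * fs)
    gains <- pmax(1 + stats::rnorm(length(ch), 0, config$channel_gain_sd), 0.5)
    out <- matrix(0, n, length(ch))
    for (j in seq_along(ch)) {
      i0 <- length(cyc) + 1 + shift[j]
      out[, j] <- gains[j] * base[i0:(i0 + n - 1)]
    }
    rms <- sqrt(mean(out^2))
    out <- out * (target_rms / rms)
    colnames(out) <- ch
    out
  })
}

# raised-cosine onset/offset taper of length ramp_n samples
taper_edges <- function(n, fs, ramp_s = 0.25) {
  w <- rep(1, n)
  rn <- min(round(ramp_s * fs), floor(n / 2))
  if (rn > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(rn) / rn))
    w[seq_len(rn)] <- ramp
    w[(n - rn + 1):n] <- rev(ramp)
  }
  w
}

#' Generate one annotated synthetic recording
#'
#' Background EEG with `n_seizures` generalized SWD seizures inserted at
#' non-overlapping times, none starting before 30 s (so the amplitude
#' reference segment stays interictal).  If `frag_fraction > 0`, a gap of
#' that fraction of each seizure's duration is implanted strictly inside
#' it and the ictal rhythm inside the gap is disrupted according to
#' `frag_mode`.  Short epileptiform bursts and frontal blink artifacts are
#' added to the interictal EEG.
#'
#' @param config A [sim_config()].
#' @param subject_id Subject identifier.
#' @param seed Seed (default `config$seed`).
#' @return List with `recording` (an [eeg_recording()]), `annotations`
#'   (an [annotation_set()] of the seizure intervals, gaps included),
#'   `gaps` (data frame of implanted fragmentation gaps) and `events`
#'   (data frame of burst/blink artifact times).
#' @export
gen_recording <- function(config = sim_config(), subject_id = "S01",
                          seed = config$seed) {
  with_seed(seed, {
    fs <- config$fs
    n <- round(config$duration_s * fs)
    scale <- stats::runif(1, config$subject_scale_range[1],
                          config$subject_scale_range[2])
    rec <- gen_background(config, n, scale)
    rec$subject_id <- subject_id
    bg_rms <- sqrt(mean(rec$data^2))

    # seizure schedule: durations from the triangular distribution, starts
    # spaced by at least min_gap_s, first no earlier than 35 s
    k <- config$n_seizures
    gaps_df <- data.frame(subject_id = character(0), onset_s = numeric(0),
                          offset_s = numeric(0), mode = character(0))
    ann <- NULL
    if (k > 0) {
      durs <- rtriangular(k, config$seizure_min_s, config$seizure_max_s,
                          config$seizure_mode_s)
      t_min <- 35
      t_max <- config$duration_s - 5
      slack <- t_max - t_min - sum(durs) - (k - 1) * config$min_gap_s
      if (slack < 0)
        stop("seizures do not fit into the recording duration")
      u <- sort(stats::runif(k))
      extra <- slack * diff(c(0, u))
      starts <- t_min + cumsum(extra) +
        c(0, cumsum(durs[-k] + config$min_gap_s))
      starts <- round(starts, 3)
      durs <- round(durs, 3)
      ann <- annotation_set(subject_id, starts, durs)

      for (i in seq_len(k)) {
        ns <- round(durs[i] * fs)
        seg <- gen_swd(durs[i], config, target_rms = config$swd_gain * bg_rms)
        mask <- taper_edges(ns, fs)
        if (config$frag_fraction > 0) {
          gap_len <- config$frag_fraction * durs[i]
          margin <- 1
          lo <- margin; hi <- durs[i] - margin - gap_len
          if (hi > lo) {
            g0 <- stats::runif(1, lo, hi)
            gi <- which(sample_times(ns, fs) >= g0 &
                          sample_times(ns, fs) < g0 + gap_len)
            if (length(gi)) {
              gm <- numeric(ns); gm[gi] <- 1
              # short ramps so the interruption is not a hard splice
              gm <- as.numeric(stats::filter(gm, rep(1 / 11, 11), sides = 2))
              gm[is.na(gm)] <- 0
              repl <- switch(config$frag_mode,
                cessation = matrix(0, ns, 19),
                spike_loss = gen_swd(durs[i], config,
                                     target_rms = config$swd_gain * bg_rms,
                                     spikes = FALSE),
                desync = gen_swd(durs[i], config,
                                 target_rms = config$swd_gain * bg_rms,
                                 uniform_jitter = TRUE))
              seg <- seg * (1 - gm) + repl * gm
              gaps_df <- rbind(gaps_df, data.frame(
                subject_id = subject_id, onset_s = starts[i] + g0,
                offset_s = starts[i] + g0 + gap_len,
                mode = config$frag_mode))
            }
          }
        }
        i0 <- round(starts[i] * fs) + 1
        rows <- i0:(i0 + ns - 1)
        rec$data[rows, ] <- rec$data[rows, ] + seg * mask
      }
    }

    # short interictal epileptiform bursts and frontal blink artifacts
    seiz <- seizure_intervals(ann, subject_id)
    free <- function(t0, t1) {
      t0 > 31 && t1 < config$duration_s - 1 &&
        (nrow(seiz) == 0 || !any(seiz[, 1] < t1 + 3 & seiz[, 2] > t0 - 3))
    }
    events <- data.frame(subject_id = character(0), onset_s = numeric(0),
                         offset_s = numeric(0), type = character(0))
    nb <- stats::rpois(1, config$burst_count)
    for (b in seq_len(nb)) {
      d <- stats::runif(1, config$burst_min_s, config$burst_max_s)
      for (try in 1:50) {
        t0 <- stats::runif(1, 31, config$duration_s - d - 1)
        if (free(t0, t0 + d)) break
        t0 <- NA
      }
      if (is.na(t0)) next
      ns <- round(d * fs)
      seg <- gen_swd(d, config, target_rms = config$burst_gain * bg_rms)
      rows <- (round(t0 * fs) + 1):(round(t0 * fs) + ns)
      rec$data[rows, ] <- rec$data[rows, ] + seg * taper_edges(ns, fs, 0.1)
      events <- rbind(events, data.frame(subject_id = subject_id,
                                         onset_s = t0, offset_s = t0 + d,
                                         type = "burst"))
    }
    nbl <- stats::rpois(1, config$blink_count)
    ch <- colnames(rec$data)
    blink_gain <- ifelse(ch %in% c("Fp1", "Fp2"), 1,
                         ifelse(ch %in% c("F7", "F8", "F3", "F4"), 0.35, 0.05))
    for (b in seq_len(nbl)) {
      d <- 0.3
      for (try in 1:50) {
        t0 <- stats::runif(1, 31, config$duration_s - d - 1)
        if (free(t0, t0 + d)) break
        t0 <- NA
      }
      if (is.na(t0)) next
      ns <- round(d * fs)
      shape <- sin(pi * seq_len(ns) / ns)^2 * 4 * bg_rms
      rows <- (round(t0 * fs) + 1):(round(t0 * fs) + ns)
      rec$data[rows, ] <- rec$data[rows, ] + outer(shape, blink_gain)
      events <- rbind(events, data.frame(subject_id = subject_id,
                                         onset_s = t0, offset_s = t0 + d,
                                         type = "blink"))
    }

    if (is.null(ann))
      ann <- validate_annotations(data.frame(
        subject_id = character(0), onset_s = numeric(0),
        offset_s = numeric(0), label = character(0)))
    list(recording = rec, annotations = ann, gaps = gaps_df, events = events)
  })
}

#' Generate a synthetic cohort
#'
#' Independent subjects with per-subject seeds derived reproducibly from
#' the master seed; the whole cohort is bit-identical under the same seed.
#'
#' @param config A [sim_config()] (`n_subjects >= 2`).
#' @return List of [gen_recording()] results, one per subject, named by
#'   subject id (`S01`, `S02`, ...).
#' @export
gen_cohort <- function(config = sim_config()) {
  n <- config$n_subjects
  if (n < 2) stop("a cohort needs at least two subjects")
  seeds <- derive_seeds(config$seed, n)
  ids <- sprintf("S%02d", seq_len(n))
  out <- lapply(seq_len(n), function(i)
    gen_recording(config, subject_id = ids[i], seed = seeds[i]))
  names(out) <- ids
  out
}

#' Extract pooled features, annotations and durations from a cohort
#'
#' Runs [segment_features()] on every subject of a [gen_cohort()] result
#' (or any list of `list(recording, annotations)` pairs) and pools the
#' outputs into the inputs expected by [loocv()].
#'
#' @param cohort List of `list(recording, annotations, ...)`.
#' @param config A [run_config()].
#' @param filter Optional [filter_spec()] applied to each recording.
#' @return List: `features` (pooled data frame), `annotations` (pooled
#'   [annotation_set()]), `durations` (named numeric vector).
#' @export
cohort_features <- function(cohort, config = run_config(), filter = NULL) {
  feats <- lapply(cohort, function(s)
    segment_features(s$recording, s$annotations, config, filter))
  anns <- do.call(rbind, lapply(cohort, function(s) as.data.frame(s$annotations)))
  durs <- vapply(cohort, function(s) duration_s(s$recording), numeric(1))
  names(durs) <- vapply(cohort, function(s) s$recording$subject_id,
                        character(1))
  list(features = do.call(rbind, feats),
       annotations = validate_annotations(anns),
       durations = durs)
}
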