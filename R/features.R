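#' Interictal amplitude reference
#'
#' The amplitude feature is normalized by `A_ref`, the mean absolute sample
#' value over the active channel subset in a 30-s interictal segment taken
#' from the beginning of the recording.  Normalization makes the feature
#' comparable across subjects whose raw EEG amplitude differs (age,
#' electrode impedance).  If the first 30 s contain an annotated seizure,
#' the first seizure-free 30-s stretch is used instead; if none exists, an
#' error is raised.
#'
#' @param rec An [eeg_recording()].
#' @param annotations An [annotation_set()] or `NULL`.
#' @param subset_name Channel subset name, see [channel_subset()].
#' @param ref_window_s Reference segment length in seconds (default 30).
#' @return List with `A_ref` (microvolts) and `window` (`c(start, end)`).
#' @export
reference_amplitude <- function(rec, annotations = NULL,
                                subset_name = "S19", ref_window_s = 30) {
  dur <- duration_s(rec)
  if (dur < ref_window_s)
    stop("recording shorter than the ", ref_window_s, "-s amplitude reference")
  seiz <- seizure_intervals(annotations, rec$subject_id)
  # candidate starts: 0 and each seizure offset; first seizure-free stretch
  cand <- sort(unique(c(0, seiz[, 2])))
  start <- NA_real_
  for (t0 in cand) {
    t1 <- t0 + ref_window_s
    if (t1 > dur + 1e-9) next
    if (nrow(seiz) == 0 || !any(seiz[, 1] < t1 & seiz[, 2] > t0)) {
      start <- t0
      break
    }
  }
  if (is.na(start))
    stop("no seizure-free ", ref_window_s, "-s stretch for amplitude reference")
  x <- channel_data(rec, channel_subset(subset_name))
  t <- sample_times(nrow(x), rec$fs)
  idx <- t >= start & t < start + ref_window_s
  list(A_ref = mean(abs(x[idx, , drop = FALSE])),
       window = c(start, start + ref_window_s))
}

#' Two classifier features of a single window
#'
#' For a half-open window `[start, end)`: the global synchronization index
#' (mean pairwise wavelet phase-locking over the subset, [global_gamma()])
#' and the normalized amplitude `Am = mean(|x|) / A_ref` averaged over the
#' subset channels and window samples.
#'
#' @param window Numeric length-2, `c(start_s, end_s)`.
#' @param phases Phase matrix from [wavelet_phases()].
#' @param rec The (preprocessed) [eeg_recording()].
#' @param subset_name Channel subset name.
#' @param A_ref Reference amplitude from [reference_amplitude()].
#' @return Named numeric: `gamma_mean`, `amplitude_norm`.
#' @export
window_features <- function(window, phases, rec, subset_name = "S19",
                            A_ref) {
  stopifnot(A_ref > 0)
  channels <- channel_subset(subset_name)
  G <- sync_matrix(phases, fs = rec$fs, channels = channels, window = window)
  x <- channel_data(rec, channels)
  t <- sample_times(nrow(x), rec$fs)
  idx <- t >= window[1] & t < window[2]
  c(gamma_mean = global_gamma(G),
    amplitude_norm = mean(abs(x[idx, , drop = FALSE])) / A_ref)
}

#' Per-window feature table for a whole recording
#'
#' The per-subject analysis pipeline: slide 1-s windows at 0.5-s step over
#' the recording, label each window against the seizure annotations
#' ([label_segments()]), compute the wavelet phases once over the full
#' recording, and evaluate the two classifier features per window.
#' Optionally applies the preprocessing filters first.
#'
#' @param rec An [eeg_recording()].
#' @param annotations An [annotation_set()] or `NULL`.
#' @param config A [run_config()].
#' @param filter A [filter_spec()] to apply first, or `NULL` to analyse the
#'   recording as given (e.g. already filtered, or simulated without line
#'   noise and drift).
#' @return Data frame with one row per window: `subject_id`, `start`,
#'   `end`, `taxonomy`, `label`, `gamma_mean`, `amplitude_norm`.
#' @export
segment_features <- function(rec, annotations = NULL, config = run_config(),
                             filter = NULL) {
  if (!is.null(filter)) rec <- preprocess(rec, filter)
  channels <- channel_subset(config$subset_name)
  x <- channel_data(rec, channels)
  fs <- rec$fs

  windows <- segment_stream(duration_s(rec), config$window_s, config$step_s)
  if (nrow(windows) == 0L)
    stop("recording shorter than one analysis window")
  windows <- label_segments(windows, annotations, rec$subject_id)
  A_ref <- reference_amplitude(rec, annotations, config$subset_name,
                               config$ref_window_s)$A_ref

  sub <- eeg_recording(x, fs, subject_id = rec$subject_id)
  phases <- wavelet_phases(sub, config$fc, config$fa)

  n <- nrow(windows)
  g <- amp <- numeric(n)
  for (i in seq_len(n)) {
    # samples with start <= (i-1)/fs < end
    i0 <- ceiling(windows$start[i] * fs - 1e-9) + 1
    i1 <- min(floor(windows$end[i] * fs - 1e-9) + 1, nrow(x))
    P <- phases[i0:i1, , drop = FALSE]
    g[i] <- global_gamma(gamma_from_phases(P))
    amp[i] <- mean(abs(x[i0:i1, , drop = FALSE])) / A_ref
  }
  data.frame(subject_id = rec$subject_id,
             start = windows$start, end = windows$end,
             taxonomy = windows$taxonomy, label = windows$label,
             gamma_mean = g, amplitude_norm = amp,
             stringsAsFactors = FALSE)
}

#' Write or read a per-window feature table as CSV
#'
#' Columns: `subject_id, start, end, taxonomy, label, gamma_mean,
#' amplitude_norm` (comma separator, header, `.` decimal).
#'
#' @param features Data frame from [segment_features()].
#' @param path CSV file path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
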