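#' Multichannel EEG recording
#'
#' Container for a multichannel scalp EEG recording: a samples-by-channels
#' numeric matrix in microvolts together with the sampling frequency,
#' channel labels (10-20 system) and a subject identifier.
#'
#' @param data Numeric matrix, samples in rows, channels in columns.
#'   Column names, if present, are used as channel labels.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param channels Character vector of unique channel labels; defaults to
#'   the column names of `data`.
#' @param subject_id Subject identifier string.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `data` (matrix, column names set to `channels`), `fs`, `subject_id`.
#' @export
#' @examples
#' x <- matrix(rnorm(500), ncol = 2, dimnames = list(NULL, c("Fp1", "Fp2")))
#' rec <- eeg_recording(x, fs = 250)
#' duration_s(rec)
eeg_recording <- function(data, fs, channels = colnames(data),
                          subject_id = "S01") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (samples x channels)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channels))
    channels <- if (ncol(data)) paste0("ch", seq_len(ncol(data)))
      else character(0)
  channels <- as.character(channels)
  if (length(channels) != ncol(data))
    stop("number of channel labels must equal ncol(data)")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  colnames(data) <- channels
  structure(list(data = data, fs = fs, subject_id = as.character(subject_id)),
            class = "eeg_recording")
}

#' @rdname eeg_recording
#' @param rec An `eeg_recording`.
#' @export
duration_s <- function(rec) nrow(rec$data) / rec$fs

#' @rdname eeg_recording
#' @export
n_channels <- function(rec) ncol(rec$data)

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels, %.1f s @ %g Hz\n",
              x$subject_id, n_channels(x), duration_s(x), x$fs))
  cat("  channels:", paste(colnames(x$data), collapse = " "), "\n")
  invisible(x)
}

# select named channels, erroring on any that are absent
channel_data <- function(rec, channels) {
  missing <- setdiff(channels, colnames(rec$data))
  if (length(missing))
    stop("recording is missing channel(s): ", paste(missing, collapse = ", "))
  rec$data[, channels, drop = FALSE]
}

# sample timestamps in seconds from recording start (first sample at t = 0)
sample_times <- function(n, fs) (seq_len(n) - 1L) / fs
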