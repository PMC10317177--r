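#' Read and write EEG recordings in EDF format
#'
#' Minimal reader/writer for the European Data Format (EDF), the de facto
#' clinical EEG interchange format: a 256-byte ASCII header, one 256-byte
#' ASCII header block per signal, and 16-bit little-endian two's-complement
#' data records.  The writer uses 1-s data records, digital range
#' -32768..32767 and a per-channel physical range covering the data, so the
#' round-trip error is at most one quantization step of that range.
#'
#' Only whole-second recordings with an integer sampling frequency can be
#' written (a consequence of the fixed 1-s record duration).
#'
#' @param path File path.
#' @param rec An [eeg_recording()] with finite samples in microvolts.
#' @return `read_edf()` returns an [eeg_recording()]; `write_edf()` returns
#'   `path` invisibly.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) stop("not a valid EDF file: ", path)
  field <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  subject_id <- field(hdr, 9, 80)
  n_records <- suppressWarnings(as.integer(field(hdr, 237, 8)))
  rec_dur   <- suppressWarnings(as.numeric(field(hdr, 245, 8)))
  ns        <- suppressWarnings(as.integer(field(hdr, 253, 4)))
  if (is.na(ns) || is.na(n_records) || is.na(rec_dur))
    stop("not a valid EDF file: malformed header in ", path)
  if (ns < 1) stop("EDF file contains no signals: ", path)

  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  sfield <- function(from, len) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, from + (i - 1) * len, from + i * len - 1)),
      character(1))
  }
  # per-signal fields are stored grouped: all labels, all transducers, ...
  off <- 0
  grab <- function(len) {
    out <- vapply(seq_len(ns), function(i) {
      a <- off + (i - 1) * len + 1
      trimws(substr(sig_hdr, a, a + len - 1))
    }, character(1))
    off <<- off + ns * len
    out
  }
  labels    <- grab(16)
  grab(80)                     # transducer
  grab(8)                      # physical dimension
  pmin <- as.numeric(grab(8))
  pmax <- as.numeric(grab(8))
  dmin <- as.numeric(grab(8))
  dmax <- as.numeric(grab(8))
  grab(80)                     # prefiltering
  nspr <- as.integer(grab(8))  # samples per record
  if (any(is.na(pmin) | is.na(pmax) | is.na(dmin) | is.na(dmax) | is.na(nspr)))
    stop("not a valid EDF file: malformed signal header in ", path)

  raw <- readBin(con, integer(), n = n_records * sum(nspr), size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_records * sum(nspr))
    stop("EDF file truncated: ", path)

  data <- matrix(0, nrow = n_records * nspr[1], ncol = ns)
  if (length(unique(nspr)) != 1L)
    stop("EDF signals have mismatched sampling rates; not supported")
  idx <- 0L
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      block <- raw[(idx + 1):(idx + nspr[s])]
      data[((r - 1) * nspr[s] + 1):(r * nspr[s]), s] <- block
      idx <- idx + nspr[s]
    }
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  for (s in seq_len(ns))
    data[, s] <- (data[, s] - dmin[s]) * scale[s] + pmin[s]
  fs <- nspr[1] / rec_dur
  labels <- sub("^EEG ", "", labels)
  eeg_recording(data, fs = fs, channels = labels,
                subject_id = if (nzchar(subject_id)) subject_id else "unknown")
}

#' @rdname read_edf
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) == 0L || nrow(rec$data) == 0L)
    stop("cannot write an empty recording")
  if (!all(is.finite(rec$data)))
    stop("recording contains non-finite samples; cannot encode as EDF")
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling frequency")
  fs <- as.integer(round(fs))
  n <- nrow(rec$data)
  if (n %% fs != 0)
    stop("EDF writer requires a whole number of seconds of data")
  n_records <- n %/% fs
  ns <- ncol(rec$data)

  # physical range per channel, rendered to <= 8 ASCII chars and re-parsed so
  # the scaling used for encoding matches the header text exactly
  fmt8 <- function(x) {
    for (d in 7:1) {
      s <- formatC(x, digits = d, format = "g", width = 1)
      if (nchar(s) <= 8) return(s)
    }
    stop("cannot encode physical range in 8 characters")
  }
  pmin_s <- pmax_s <- character(ns)
  pmin <- pmax <- numeric(ns)
  for (s in seq_len(ns)) {
    r <- range(rec$data[, s])
    if (r[1] == r[2]) r <- r + c(-1, 1)
    r <- r + c(-1, 1) * diff(r) * 1e-4   # guard against round-down clipping
    pmin_s[s] <- fmt8(r[1]); pmax_s[s] <- fmt8(r[2])
    pmin[s] <- as.numeric(pmin_s[s]); pmax[s] <- as.numeric(pmax_s[s])
    if (!(pmin[s] < pmax[s])) stop("degenerate physical range after rounding")
  }
  dmin <- -32768; dmax <- 32767

  pad <- function(x, w) formatC(as.character(x), width = -w, flag = " ")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(pad("0", 8))
  wr(pad(rec$subject_id, 80))
  wr(pad("swdsync", 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 * (1 + ns), 8))
  wr(pad("", 44))
  wr(pad(n_records, 8))
  wr(pad("1", 8))
  wr(pad(ns, 4))
  wr(paste0(pad(colnames(rec$data), 16), collapse = ""))
  wr(paste0(pad(rep("", ns), 80), collapse = ""))
  wr(paste0(pad(rep("uV", ns), 8), collapse = ""))
  wr(paste0(pad(pmin_s, 8), collapse = ""))
  wr(paste0(pad(pmax_s, 8), collapse = ""))
  wr(paste0(pad(rep(dmin, ns), 8), collapse = ""))
  wr(paste0(pad(rep(dmax, ns), 8), collapse = ""))
  wr(paste0(pad(rep("", ns), 80), collapse = ""))
  wr(paste0(pad(rep(fs, ns), 8), collapse = ""))
  wr(paste0(pad(rep("", ns), 32), collapse = ""))

  # digital encoding, record-interleaved
  dig <- matrix(0L, nrow = n, ncol = ns)
  for (s in seq_len(ns)) {
    d <- round((rec$data[, s] - pmin[s]) / (pmax[s] - pmin[s]) *
                 (dmax - dmin) + dmin)
    dig[, s] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  out <- integer(n * ns)
  pos <- 0L
  for (r in seq_len(n_records)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      out[(pos + 1):(pos + fs)] <- dig[rows, s]
      pos <- pos + fs
    }
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Quantization step of an EDF-encoded channel
#'
#' The physical value of one digital unit given the encoded physical range;
#' the maximum round-trip error of [write_edf()] + [read_edf()] is half of
#' one step per sample (one step is asserted in tests as a safe bound).
#'
#' @param phys_range Numeric length-2: physical min and max actually written.
#' @return Quantization step in physical units (microvolts).
#' @export
edf_quantization_step <- function(phys_range) {
  diff(range(phys_range)) / (32767 - (-32768))
}
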