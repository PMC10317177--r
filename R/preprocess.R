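#' Preprocessing filter specification
#'
#' Two causal IIR filters are applied before analysis: a second-order notch
#' that removes power-line interference and a 6th-order high-pass
#' Butterworth (cutoff 0.5 Hz) that removes baseline drift.  The notch is a
#' standard biquad with quality factor `notch_q` (default 35, bandwidth
#' about 1.4 Hz at 50 Hz), narrow enough to leave beta/gamma activity
#' untouched.  Filtering is forward-only (causal) so the pipeline can run on
#' a live data stream; group delay is not compensated.
#'
#' @param notch_freq Power-line frequency in Hz (50 in Europe).
#' @param notch_q Notch quality factor (center frequency / -3 dB bandwidth).
#' @param hp_cutoff High-pass cutoff in Hz.
#' @param hp_order High-pass Butterworth order.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 35,
                        hp_cutoff = 0.5, hp_order = 6L) {
  stopifnot(notch_freq > 0, notch_q > 0, hp_cutoff > 0, hp_order >= 1)
  if (hp_cutoff >= notch_freq)
    stop("high-pass cutoff must be below the notch frequency")
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 hp_cutoff = hp_cutoff, hp_order = as.integer(hp_order)),
            class = "filter_spec")
}

# biquad notch coefficients (constrained direct-form II transposed biquad)
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

apply_channelwise <- function(rec, fun) {
  if (ncol(rec$data) == 0L || nrow(rec$data) == 0L) return(rec)
  out <- rec
  for (j in seq_len(ncol(rec$data)))
    out$data[, j] <- fun(rec$data[, j])
  out
}

#' Remove power-line noise with a second-order IIR notch
#'
#' @param rec An [eeg_recording()].
#' @param spec A [filter_spec()].
#' @return Filtered [eeg_recording()] of the same shape.
#' @export
notch_filter <- function(rec, spec = filter_spec()) {
  if (spec$notch_freq >= rec$fs / 2)
    stop("notch frequency must be below the Nyquist frequency")
  co <- notch_coefficients(spec$notch_freq, rec$fs, spec$notch_q)
  apply_channelwise(rec, function(x)
    as.numeric(signal::filter(co$b, co$a, x)))
}

# High-pass Butterworth as cascaded biquads (second-order sections).  A
# single order-6 transfer function with a 0.5-Hz cutoff at a 250-Hz rate is
# numerically ill-conditioned (poles clustered near z = 1); the cascade
# keeps each stage well-conditioned.  Bilinear transform with cutoff
# prewarping; analog prototype poles exp(i*pi*(2k + n - 1)/(2n)).
butter_highpass_sos <- function(order, fc, fs) {
  wc <- 2 * fs * tan(pi * fc / fs)   # prewarped analog cutoff
  K <- 2 * fs
  sos <- list()
  bilinear_sec <- function(c2, c1, c0, d2, d1, d0) {
    b <- c(c2 * K^2 + c1 * K + c0, -2 * c2 * K^2 + 2 * c0,
           c2 * K^2 - c1 * K + c0)
    a <- c(d2 * K^2 + d1 * K + d0, -2 * d2 * K^2 + 2 * d0,
           d2 * K^2 - d1 * K + d0)
    list(b = b / a[1], a = a / a[1])
  }
  n_pairs <- order %/% 2
  for (k in seq_len(n_pairs)) {
    # conjugate prototype pole pair -> s^2 + a1 s + 1; HP: s^2/(s^2+a1*wc*s+wc^2)
    a1 <- -2 * Re(exp(1i * pi * (2 * k + order - 1) / (2 * order)))
    sos[[length(sos) + 1]] <- bilinear_sec(1, 0, 0, 1, a1 * wc, wc^2)
  }
  if (order %% 2 == 1) {
    # real pole at -1 -> first-order section s/(s + wc)
    b <- c(K, -K) / (K + wc)
    a <- c(1, (wc - K) / (K + wc))
    sos[[length(sos) + 1]] <- list(b = c(b, 0), a = c(a, 0))
  }
  sos
}

#' Remove baseline drift with a high-pass Butterworth filter
#'
#' @inheritParams notch_filter
#' @export
highpass_filter <- function(rec, spec = filter_spec()) {
  if (spec$hp_cutoff >= rec$fs / 2)
    stop("high-pass cutoff must be below the Nyquist frequency")
  sos <- butter_highpass_sos(spec$hp_order, spec$hp_cutoff, rec$fs)
  apply_channelwise(rec, function(x) {
    for (sec in sos) x <- as.numeric(signal::filter(sec$b, sec$a, x))
    x
  })
}

#' Full preprocessing: high-pass then notch
#'
#' Applied per channel, causally, with zero initial filter state; no samples
#' are dropped (transients decay within the first seconds and tests discard
#' them explicitly).  The two linear stages commute; high-pass is applied
#' first so the drift is gone before the notch transient.
#'
#' @inheritParams notch_filter
#' @export
preprocess <- function(rec, spec = filter_spec()) {
  notch_filter(highpass_filter(rec, spec), spec)
}
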