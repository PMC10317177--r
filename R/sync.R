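#' Pairwise phase-synchronization index
#'
#' The stability of the phase difference \eqn{\Delta\phi = \phi_k - \phi_l}
#' over a window is measured by the resultant length
#' \deqn{\gamma(k,l) = \sqrt{\langle\sin\Delta\phi\rangle^2 +
#'   \langle\cos\Delta\phi\rangle^2} \in [0, 1],}
#' where the angle brackets are temporal averages.  A uniform
#' phase-difference distribution gives \eqn{\gamma = 0} (independent
#' channels); a constant phase difference gives \eqn{\gamma = 1} (perfect
#' phase locking).  Samples where either phase is `NA` (undefined phase at
#' vanishing wavelet magnitude) are excluded from the averages.
#'
#' @param phi_k,phi_l Equal-length numeric phase series in radians; `NA`
#'   marks invalid samples.
#' @return The synchronization index, a scalar in `[0, 1]`.
#' @export
#' @examples
#' pairwise_gamma(rep(0.3, 100), rep(1.2, 100))        # locked: 1
#' pairwise_gamma(2 * pi * (0:99) / 100, rep(0, 100))  # uniform grid: 0
pairwise_gamma <- function(phi_k, phi_l) {
  if (length(phi_k) != length(phi_l))
    stop("phase series must have equal length")
  d <- phi_k - phi_l
  d <- d[is.finite(d)]
  if (length(d) == 0L)
    stop("no valid phase samples in window; synchronization undefined")
  g <- sqrt(mean(sin(d))^2 + mean(cos(d))^2)
  min(g, 1)
}

#' Pairwise synchronization matrix over a channel subset
#'
#' Computes \eqn{\gamma(k,l)} for all unordered channel pairs of a subset,
#' from a samples-by-channels phase matrix, optionally restricted to the
#' samples whose timestamps fall in a half-open window `[start, end)`.
#' Internally the matrix of resultant lengths is obtained in one complex
#' matrix product, \eqn{\gamma(k,l) = |\sum_t e^{i(\phi_l - \phi_k)}| / n},
#' with invalid samples handled per pair.
#'
#' @param phases Numeric matrix (samples x channels) of phases with channel
#'   names as column names, e.g. from [wavelet_phases()].
#' @param fs Sampling frequency in Hz (needed only when `window` is given).
#' @param channels Channel labels to use (default: all columns).
#' @param window Optional numeric length-2, `c(start_s, end_s)`; samples
#'   with `start_s <= t < end_s` enter the averages.
#' @return A symmetric numeric matrix of class `sync_matrix` with unit
#'   diagonal; entries are `NA` for pairs with no valid common samples.
#' @export
sync_matrix <- function(phases, fs = NULL, channels = colnames(phases),
                        window = NULL) {
  if (is.null(channels))
    stop("`phases` must have channel names (or pass `channels`)")
  missing <- setdiff(channels, colnames(phases))
  if (length(missing))
    stop("phases are missing channel(s): ", paste(missing, collapse = ", "))
  P <- phases[, channels, drop = FALSE]
  if (!is.null(window)) {
    if (is.null(fs)) stop("`fs` is required when `window` is given")
    t <- sample_times(nrow(P), fs)
    P <- P[t >= window[1] & t < window[2], , drop = FALSE]
  }
  if (nrow(P) == 0L) stop("window contains no samples")
  G <- gamma_from_phases(P)
  structure(G, class = c("sync_matrix", class(G)), window = window)
}

# core: gamma matrix from a (samples x channels) phase matrix, NA-aware
gamma_from_phases <- function(P) {
  ok <- is.finite(P)
  Z <- matrix(complex(real = 0), nrow(P), ncol(P))
  Z[ok] <- exp(1i * P[ok])
  C <- t(Conj(Z)) %*% Z
  Nv <- crossprod(ok * 1)
  G <- Mod(C) / Nv
  G[Nv == 0] <- NA_real_
  G <- pmin(G, 1)
  dim(G) <- dim(C)
  diag(G) <- 1
  dimnames(G) <- list(colnames(P), colnames(P))
  G
}

#' Global and channel synchronization indices
#'
#' `global_gamma()` is the average of the off-diagonal entries of the
#' synchronization matrix, i.e. the mean of the `N(N-1)/2` upper-triangle
#' pairwise indices.  `channel_gamma()` is the average pairwise index of one
#' channel with the `N-1` others (used for topographic maps).  Both divide
#' by the number of terms so the indices stay in `[0, 1]`.  Pairs flagged
#' `NA` are excluded; if every pair is invalid an error is raised.
#'
#' @param mat A [sync_matrix()] (any symmetric matrix with unit diagonal).
#' @param k Channel label or column index.
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' m <- matrix(0.5, 4, 4); diag(m) <- 1
#' global_gamma(m)    # 0.5
#' channel_gamma(m, 2)
global_gamma <- function(mat) {
  v <- mat[upper.tri(mat)]
  if (all(is.na(v))) stop("all channel pairs invalid; global gamma undefined")
  mean(v, na.rm = TRUE)
}

#' @rdname global_gamma
#' @export
channel_gamma <- function(mat, k) {
  if (is.character(k)) {
    k <- match(k, colnames(mat))
    if (is.na(k)) stop("channel not in the subset")
  }
  if (k < 1 || k > ncol(mat)) stop("channel index out of range")
  v <- mat[k, -k]
  if (all(is.na(v))) stop("all pairs of channel invalid")
  mean(v, na.rm = TRUE)
}
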