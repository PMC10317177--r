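# Independent oracles used across the suite.  These deliberately share no
# code with the package: the CWT oracle is a direct time-domain Riemann-sum
# convolution, the synchronization oracles are explicit enumerations, and
# the post-processing oracle works on run-length encodings.

# direct time-domain CWT (truncated at |t/a| <= 6), no padding
oracle_cwt <- function(x, fs, fc, fa) {
  a <- fc / fa
  K <- ceiling(6 * a * fs)
  u <- (-K:K) / (a * fs)
  psi_conj <- Conj(pi^(-0.25) * exp(2i * pi * fc * u) * exp(-u^2 / 2))
  n <- length(x)
  out <- complex(n)
  for (j in seq_len(n)) {
    k <- (-K):K
    idx <- j + k
    ok <- idx >= 1 & idx <= n
    out[j] <- sum(x[idx[ok]] * psi_conj[ok]) / (a * fs)
  }
  out
}

# gamma between two signals via the direct CWT with 1-s reflect padding
oracle_gamma_signals <- function(x1, x2, fs, fc, fa) {
  pad <- function(x) {
    n <- length(x); p <- min(fs, n - 1)
    c(rev(x[2:(p + 1)]), x, rev(x[(n - p):(n - 1)]))
  }
  n <- length(x1); p <- min(fs, n - 1)
  T1 <- oracle_cwt(pad(x1), fs, fc, fa)[(p + 1):(p + n)]
  T2 <- oracle_cwt(pad(x2), fs, fc, fa)[(p + 1):(p + n)]
  d <- atan2(Im(T1), Re(T1)) - atan2(Im(T2), Re(T2))
  sqrt(mean(sin(d))^2 + mean(cos(d))^2)
}

# mean off-diagonal entry by explicit double loop
oracle_global_gamma <- function(mat) {
  n <- ncol(mat)
  s <- 0; cnt <- 0
  for (k in 1:(n - 1)) for (l in (k + 1):n) {
    s <- s + mat[k, l]; cnt <- cnt + 1
  }
  s / cnt
}

oracle_channel_gamma <- function(mat, k) {
  s <- 0; cnt <- 0
  for (l in seq_len(ncol(mat))) if (l != k) {
    s <- s + mat[k, l]; cnt <- cnt + 1
  }
  s / cnt
}

# brute-force k-NN: per-query loop, full sort, majority with interictal ties
oracle_knn <- function(train_x, train_y, query, k, center, scale) {
  xs <- sweep(sweep(train_x, 2, center), 2, scale, "/")
  qs <- sweep(sweep(query, 2, center), 2, scale, "/")
  out <- character(nrow(qs))
  for (i in seq_len(nrow(qs))) {
    d <- sqrt(rowSums((xs - matrix(qs[i, ], nrow(xs), 2, byrow = TRUE))^2))
    nb <- train_y[order(d)[1:k]]
    out[i] <- if (sum(nb == "ictal") > k / 2) "ictal" else "interictal"
  }
  out
}

# run-length oracle for FP/MT counting and isolated-window removal
oracle_fp_mt <- function(dec_ictal, taxonomy) {
  mis <- dec_ictal & taxonomy == 0
  fp <- sum(mis)
  mt <- 0
  prev <- FALSE
  for (v in mis) {
    if (v && !prev) mt <- mt + 1
    prev <- v
  }
  list(FP = fp, MT = mt)
}

oracle_postprocess <- function(dec_ictal) {
  r <- rle(dec_ictal)
  r$values[r$values & r$lengths == 1] <- FALSE
  inverse.rle(r)
}

# all binary sequences of length n as a logical matrix (rows)
all_binary_sequences <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  dimnames(m) <- NULL
  m
}
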