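#' Wavelet-parameter grid search
#'
#' For every `(fc, fa)` combination, computes the global synchronization of
#' each analysis window and evaluates the percentage difference between the
#' mean ictal and mean interictal synchronization,
#' `100 * (mean ictal - mean interictal) / mean interictal`
#' (windows are labelled ictal when they overlap an annotated seizure).
#' Returns the full objective surface and the maximizing pair.  The default
#' grid brackets the band where the ictal-interictal contrast of
#' spike-and-wave EEG peaks (`fc` 0.6-2 Hz, `fa` 5-20 Hz).
#'
#' @param recordings A single [eeg_recording()] or a list of them
#'   (preprocessed as desired).
#' @param annotations Pooled [annotation_set()]; both ictal and interictal
#'   windows must be present.
#' @param fc_grid,fa_grid Numeric grids in Hz.
#' @param config A [run_config()] (windowing parameters are used; its
#'   `fc`/`fa` are ignored).
#' @return List of class `swd_grid_search`: `fc_grid`, `fa_grid`,
#'   `objective` (matrix, rows = `fc_grid`, cols = `fa_grid`),
#'   `best` (named vector `fc`, `fa`).
#' @export
grid_search <- function(recordings, annotations,
                        fc_grid = seq(0.6, 2, by = 0.2),
                        fa_grid = 5:20,
                        config = run_config()) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  obj <- matrix(NA_real_, length(fc_grid), length(fa_grid),
                dimnames = list(fc_grid, fa_grid))
  # window labels are parameter-independent; compute once per recording
  labs <- lapply(recordings, function(rec) {
    w <- segment_stream(duration_s(rec), config$window_s, config$step_s)
    label_segments(w, annotations, rec$subject_id)
  })
  all_lab <- unlist(lapply(labs, function(w) w$label))
  if (!any(all_lab == "ictal") || !any(all_lab == "interictal"))
    stop("grid search needs both ictal and interictal windows")
  channels <- channel_subset(config$subset_name)
  for (i in seq_along(fc_grid)) for (j in seq_along(fa_grid)) {
    g <- unlist(lapply(seq_along(recordings), function(r) {
      rec <- recordings[[r]]
      phases <- wavelet_phases(rec, fc_grid[i], fa_grid[j])[
        , channels, drop = FALSE]
      w <- labs[[r]]
      vapply(seq_len(nrow(w)), function(m) {
        i0 <- ceiling(w$start[m] * rec$fs - 1e-9) + 1
        i1 <- min(floor(w$end[m] * rec$fs - 1e-9) + 1, nrow(phases))
        global_gamma(gamma_from_phases(phases[i0:i1, , drop = FALSE]))
      }, numeric(1))
    }))
    m_ict <- mean(g[all_lab == "ictal"])
    m_int <- mean(g[all_lab == "interictal"])
    obj[i, j] <- 100 * (m_ict - m_int) / m_int
  }
  best <- which(obj == max(obj), arr.ind = TRUE)[1, ]
  structure(list(fc_grid = fc_grid, fa_grid = fa_grid, objective = obj,
                 best = c(fc = fc_grid[best[1]], fa = fa_grid[best[2]])),
            class = "swd_grid_search")
}
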