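#' Sliding analysis windows
#'
#' Partition `[0, duration_s)` into half-open windows of length `window_s`
#' starting at multiples of `step_s` (defaults: 1-s windows, 0.5-s step,
#' i.e. half-window overlap to emulate live-stream analysis).  The last
#' window starts at the largest multiple of `step_s` not exceeding
#' `duration_s - window_s`; an integer duration `d >= 1` yields `2 d - 1`
#' windows at the defaults.
#'
#' @param duration_s Recording duration in seconds.
#' @param window_s Window length in seconds.
#' @param step_s Step between window starts in seconds.
#' @return Data frame with columns `start`, `end` (half-open, seconds);
#'   zero rows if the recording is shorter than one window.
#' @export
#' @examples
#' nrow(segment_stream(10))   # 19
segment_stream <- function(duration_s, window_s = 1, step_s = 0.5) {
  if (duration_s < window_s)
    return(data.frame(start = numeric(0), end = numeric(0)))
  n <- floor((duration_s - window_s) / step_s + 1e-9) + 1
  start <- step_s * (seq_len(n) - 1)
  data.frame(start = start, end = start + window_s)
}

#' Window taxonomy relative to annotated seizures
#'
#' Assigns each window a code describing its position relative to the
#' seizures: 0 = touches no seizure; at each seizure, leading windows that
#' partially overlap its onset get 1 then 2; the first window fully embedded
#' in the seizure gets 3, interior embedded windows 4, the last embedded
#' window 5; trailing partial-overlap windows get 6 then 7.  "Overlap"
#' means nonempty interior intersection of half-open intervals, so a window
#' whose boundary merely touches a seizure is interictal.  Codes 2 and 6
#' exist only when two partial windows flank the respective boundary (e.g.
#' a seizure onset aligned to the window grid leaves a single leading
#' partial window, coded 1; a single trailing partial window is coded 7).
#' A seizure shorter than one window has no embedded windows; its partial
#' windows are coded 1, 2, 6, 7 in window order (leading codes first), a
#' documented degenerate case.  A window touched by two seizures keeps the
#' code of the earlier one.
#'
#' The binary label used for testing is `"ictal"` iff the code is nonzero:
#' any window that even partially overlaps a seizure counts as ictal ground
#' truth.
#'
#' @param windows Data frame from [segment_stream()].
#' @param annotations An [annotation_set()] (seizure rows are used), or
#'   `NULL` for none.
#' @param subject_id Restrict annotations to this subject (default: all).
#' @return `windows` with added integer column `taxonomy` and character
#'   column `label` (`"ictal"`/`"interictal"`).
#' @export
label_segments <- function(windows, annotations = NULL, subject_id = NULL) {
  code <- integer(nrow(windows))
  seiz <- seizure_intervals(annotations, subject_id)
  for (i in seq_len(nrow(seiz))) {
    on <- seiz[i, 1]; off <- seiz[i, 2]
    ov <- which(windows$start < off & windows$end > on)
    if (!length(ov)) next
    ov <- ov[order(windows$start[ov])]
    emb <- ov[windows$start[ov] >= on & windows$end[ov] <= off]
    codes <- integer(length(ov))
    names(codes) <- as.character(ov)
    if (length(emb)) {
      lead <- ov[windows$start[ov] < on]
      trail <- ov[windows$end[ov] > off]
      codes[as.character(lead)] <- seq(1L, length.out = length(lead))
      codes[as.character(emb)] <- 4L
      codes[as.character(emb[1])] <- 3L
      if (length(emb) > 1) codes[as.character(emb[length(emb)])] <- 5L
      codes[as.character(trail)] <- if (length(trail) >= 2)
        seq(6L, length.out = length(trail)) else rep(7L, length(trail))
    } else {
      # degenerate: seizure shorter than one window, all overlaps partial
      m <- length(ov)
      codes[] <- switch(min(m, 4),
                        1L, c(1L, 7L), c(1L, 2L, 7L), c(1L, 2L, 6L, 7L))
      if (m > 4) codes[] <- c(1L, 2L, rep(2L, m - 4), 6L, 7L)
    }
    keep <- ov[code[ov] == 0L]        # earlier seizure wins
    code[keep] <- codes[as.character(keep)]
  }
  windows$taxonomy <- code
  windows$label <- ifelse(code != 0L, "ictal", "interictal")
  windows
}
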