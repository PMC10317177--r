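#' OR-merge overlapping window decisions into a timeline
#'
#' Consecutive 1-s windows at 0.5-s step share a half-second; the merged
#' status of each 0.5-s half-interval of the recording is ictal if at least
#' one covering window was classified ictal (logical OR).
#'
#' @param starts Window start times in seconds (ordered, on the step grid).
#' @param decisions Character or logical window decisions, same length.
#' @param duration_s Recording duration in seconds.
#' @param window_s,step_s Windowing parameters (defaults 1 and 0.5).
#' @return Data frame with columns `start`, `end`, `ictal` (logical), one
#'   row per half-interval covering `[0, duration_s)`.
#' @export
merge_timeline <- function(starts, decisions, duration_s,
                           window_s = 1, step_s = 0.5) {
  lg <- if (is.logical(decisions)) decisions else decisions == "ictal"
  m <- ceiling(duration_s / step_s - 1e-9)
  ict <- logical(m)
  per <- round(window_s / step_s)
  for (i in which(lg)) {
    j0 <- round(starts[i] / step_s)
    cover <- (j0 + 1):(j0 + per)
    cover <- cover[cover >= 1 & cover <= m]
    ict[cover] <- TRUE
  }
  hs <- step_s * (seq_len(m) - 1)
  data.frame(start = hs, end = pmin(hs + step_s, duration_s), ictal = ict)
}

# total length of the intersection of the ictal timeline with intervals
overlap_duration <- function(timeline, intervals) {
  if (nrow(intervals) == 0) return(0)
  tl <- timeline[timeline$ictal, , drop = FALSE]
  if (nrow(tl) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(intervals))) {
    tot <- tot + sum(pmax(0, pmin(tl$end, intervals[i, 2]) -
                            pmax(tl$start, intervals[i, 1])))
  }
  tot
}

#' Detection overlap and false-positive metrics
#'
#' `ovr()` is the percentage of the total annotated seizure time covered by
#' the ictal-classified OR-merged timeline.  `perr()` is the percentage of
#' the non-seizure time falsely marked ictal.  `count_fp_mt()` counts, on
#' the raw window decisions, the number of interictal windows (taxonomy 0)
#' classified ictal (FP) and the number of maximal consecutive runs of such
#' windows (MT).
#'
#' @param timeline Data frame from [merge_timeline()].
#' @param seizures Two-column matrix of seizure intervals
#'   (see [seizure_intervals()]).
#' @return `ovr()` and `perr()` return percentages; `ovr()` returns `NA`
#'   when there are no seizures.
#' @export
ovr <- function(timeline, seizures) {
  if (nrow(seizures) == 0) return(NA_real_)
  total <- sum(seizures[, 2] - seizures[, 1])
  100 * overlap_duration(timeline, seizures) / total
}

#' @rdname ovr
#' @param total_duration_s Total recording duration in seconds.
#' @export
perr <- function(timeline, seizures, total_duration_s) {
  nonseiz <- total_duration_s - sum(seizures[, 2] - seizures[, 1])
  if (nonseiz <= 0) stop("no non-seizure time; PERR undefined")
  ict_total <- sum(timeline$end[timeline$ictal] - timeline$start[timeline$ictal])
  fp_time <- ict_total - overlap_duration(timeline, seizures)
  100 * fp_time / nonseiz
}

#' @rdname ovr
#' @param decisions Window decisions (character or logical).
#' @param taxonomy Integer taxonomy codes aligned with `decisions`.
#' @export
count_fp_mt <- function(decisions, taxonomy) {
  lg <- if (is.logical(decisions)) decisions else decisions == "ictal"
  mis <- lg & taxonomy == 0L
  r <- rle(mis)
  list(FP = sum(mis), MT = sum(r$values))
}

#' Seizure fragmentation of an abnormal-activity interval
#'
#' Applied to detector output computed with post-processing turned off:
#' the fragmentation of an interval is
#' `SFRAG = 100 - OVR`, where OVR is the percentage of the interval covered
#' by the ictal-classified OR-merged timeline.  A fully recognised,
#' continuous discharge gives SFRAG near 0; interruptions of the ictal
#' rhythm (lost spikes, transient cessation, lost synchronization) raise
#' it.  Interruptions shorter than about 0.5 s are generally below the
#' windowing resolution and go undetected.
#'
#' @param timeline Data frame from [merge_timeline()] of raw
#'   (non-post-processed) decisions.
#' @param interval Numeric length-2 `c(start_s, end_s)` of the abnormal
#'   activity.
#' @param window_s Analysis window length (an interval shorter than one
#'   window has undefined fragmentation and yields `NA`).
#' @return SFRAG percentage in `[0, 100]`, or `NA`.
#' @export
sfrag <- function(timeline, interval, window_s = 1) {
  len <- interval[2] - interval[1]
  if (len < window_s) return(NA_real_)
  cov <- overlap_duration(timeline, matrix(interval, ncol = 2))
  100 - 100 * cov / len
}

#' Per-subject detection metrics
#'
#' Computes OVR, PERR, FP, MT and the per-seizure detection indicator for
#' one subject's window decisions.  FP/MT are counted on the window
#' decisions; OVR and PERR on the OR-merged timeline.  A seizure counts as
#' found when at least one window overlapping it is classified ictal.
#'
#' @param windows Data frame with `start`, `end`, `taxonomy` for the
#'   subject's windows (ordered by start).
#' @param decisions Window decisions aligned with `windows`.
#' @param annotations Pooled [annotation_set()].
#' @param duration_s Recording duration in seconds.
#' @param config A [run_config()].
#' @return One-row data frame: `subject_id`, `OVR`, `PERR`, `FP`, `MT`,
#'   `n_seizures`, `n_found`.
#' @export
subject_metrics <- function(windows, decisions, annotations, duration_s,
                            config = run_config()) {
  sub <- windows$subject_id[1]
  seiz <- seizure_intervals(annotations, sub)
  tl <- merge_timeline(windows$start, decisions, duration_s,
                       config$window_s, config$step_s)
  fpmt <- count_fp_mt(decisions, windows$taxonomy)
  lg <- if (is.logical(decisions)) decisions else decisions == "ictal"
  found <- vapply(seq_len(nrow(seiz)), function(i) {
    any(lg & windows$start < seiz[i, 2] & windows$end > seiz[i, 1])
  }, logical(1))
  data.frame(subject_id = sub,
             OVR = ovr(tl, seiz),
             PERR = perr(tl, seiz, duration_s),
             FP = fpmt$FP, MT = fpmt$MT,
             n_seizures = nrow(seiz), n_found = sum(found),
             stringsAsFactors = FALSE)
}

#' Fragmentation of every annotated interval of a subject
#'
#' Convenience wrapper for retrospective fragmentation analysis: merges the
#' raw (non-post-processed) decisions and evaluates [sfrag()] on each
#' annotated interval (label `"abnormal"` if present, else the seizure
#' intervals).
#'
#' @param windows Data frame with `start`, `end` for the subject's windows.
#' @param decisions_raw Raw window decisions (no post-processing).
#' @param annotations Pooled [annotation_set()].
#' @param duration_s Recording duration in seconds.
#' @param config A [run_config()].
#' @return Data frame: `subject_id`, `onset_s`, `offset_s`, `sfrag`.
#' @export
fragmentation <- function(windows, decisions_raw, annotations, duration_s,
                          config = run_config()) {
  sub <- windows$subject_id[1]
  lab <- if (any(annotations$label == "abnormal" &
                   annotations$subject_id == sub)) "abnormal" else "seizure"
  iv <- seizure_intervals(annotations, sub, label = lab)
  tl <- merge_timeline(windows$start, decisions_raw, duration_s,
                       config$window_s, config$step_s)
  sf <- vapply(seq_len(nrow(iv)), function(i)
    sfrag(tl, iv[i, ], config$window_s), numeric(1))
  data.frame(subject_id = sub, onset_s = iv[, 1], offset_s = iv[, 2],
             sfrag = sf, stringsAsFactors = FALSE)
}
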