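#' Seizure and abnormal-activity annotations
#'
#' Annotations are half-open time intervals `[onset_s, offset_s)` in seconds
#' from recording start, labelled `"seizure"` or `"abnormal"`.  Two intervals
#' overlap when their interiors intersect, so an interval ending at `t` and
#' another starting at `t` are adjacent, not overlapping.
#'
#' @param subject_id Subject identifier (recycled).
#' @param onset_s Numeric vector of interval onsets in seconds.
#' @param duration_s Numeric vector of strictly positive durations.
#' @param label Character vector, `"seizure"` or `"abnormal"` (recycled).
#' @return A data frame of class `annotation_set` with columns
#'   `subject_id`, `onset_s`, `offset_s`, `label`.
#' @export
#' @examples
#' ann <- annotation_set("P1", onset_s = c(40, 90), duration_s = c(10, 8))
#' ann
annotation_set <- function(subject_id, onset_s, duration_s,
                           label = "seizure") {
  onset_s <- as.numeric(onset_s)
  duration_s <- as.numeric(duration_s)
  n <- length(onset_s)
  ann <- data.frame(subject_id = rep_len(as.character(subject_id), n),
                    onset_s = onset_s,
                    offset_s = onset_s + duration_s,
                    label = rep_len(as.character(label), n),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  need <- c("subject_id", "onset_s", "offset_s", "label")
  if (!all(need %in% names(ann)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  if (nrow(ann)) {
    if (any(!is.finite(ann$onset_s)) || any(!is.finite(ann$offset_s)))
      stop("annotation onsets/offsets must be finite")
    if (any(ann$offset_s <= ann$onset_s))
      stop("annotation durations must be strictly positive")
    bad <- setdiff(unique(ann$label), c("seizure", "abnormal"))
    if (length(bad))
      stop("unknown annotation label(s): ", paste(bad, collapse = ", "))
    for (sub in unique(ann$subject_id)) {
      for (lab in unique(ann$label)) {
        a <- ann[ann$subject_id == sub & ann$label == lab, , drop = FALSE]
        if (nrow(a) > 1) {
          a <- a[order(a$onset_s), ]
          if (any(a$onset_s[-1] < a$offset_s[-nrow(a)]))
            stop("overlapping ", lab, " intervals for subject ", sub)
        }
      }
    }
  }
  class(ann) <- c("annotation_set", "data.frame")
  ann
}

#' Read or write annotations as CSV
#'
#' The CSV dialect is fixed: comma separator, header row, `.` decimal mark,
#' columns `subject_id, onset_s, duration_s, label`.
#'
#' @param path CSV file path.
#' @param ann An [annotation_set()].
#' @return `read_annotations()` returns an [annotation_set()];
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "onset_s", "duration_s", "label")
  if (!all(need %in% names(df)))
    stop("annotation CSV needs columns: ", paste(need, collapse = ", "))
  annotation_set(df$subject_id, df$onset_s, df$duration_s, df$label)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  ann <- validate_annotations(ann)
  out <- data.frame(subject_id = ann$subject_id,
                    onset_s = ann$onset_s,
                    duration_s = ann$offset_s - ann$onset_s,
                    label = ann$label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# seizure intervals for one subject as a two-column matrix [onset, offset)
seizure_intervals <- function(ann, subject_id = NULL, label = "seizure") {
  if (is.null(ann) || nrow(ann) == 0)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("onset_s", "offset_s"))))
  keep <- ann$label == label
  if (!is.null(subject_id)) keep <- keep & ann$subject_id == subject_id
  a <- ann[keep, , drop = FALSE]
  a <- a[order(a$onset_s), , drop = FALSE]
  cbind(onset_s = a$onset_s, offset_s = a$offset_s)
}
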