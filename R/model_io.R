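#' Save and load a fitted detector as a flat text archive
#'
#' The archive is a plain-text file: a `key: value` header (k, scaler
#' center/scale, interictal threshold) followed by the training rows as
#' CSV (`gamma_mean, amplitude_norm, label, subject_id`), so separate
#' `train` and `detect` command-line invocations can share a model.
#'
#' @param model An `swd_knn` model from [knn_fit()].
#' @param path Archive file path.
#' @return `read_knn_model()` returns an `swd_knn` model;
#'   `write_knn_model()` returns `path` invisibly.
#' @export
write_knn_model <- function(model, path) {
  stopifnot(inherits(model, "swd_knn"))
  ts <- model$ts
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(formatC(x, digits = 17, format = "g"),
                           collapse = ",")
  writeLines(c(
    "format: swdsync-knn-1",
    paste0("k: ", model$k),
    paste0("center: ", num(ts$center)),
    paste0("scale: ", num(ts$scale)),
    paste0("threshold: ", num(ts$threshold)),
    "rows:",
    "gamma_mean,amplitude_norm,label,subject_id",
    paste(formatC(ts$x[, 1], digits = 17, format = "g"),
          formatC(ts$x[, 2], digits = 17, format = "g"),
          ts$y, ts$subject_id, sep = ",")), con)
  invisible(path)
}

#' @rdname write_knn_model
#' @export
read_knn_model <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "format: swdsync-knn-1"))
    stop("not an swdsync k-NN model archive: ", path)
  val <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)[1]
    sub(paste0("^", key, ": "), "", ln)
  }
  nums <- function(key) as.numeric(strsplit(val(key), ",")[[1]])
  hdr <- which(lines == "rows:")
  rows <- utils::read.csv(text = lines[(hdr + 1):length(lines)],
                          stringsAsFactors = FALSE)
  x <- as.matrix(rows[, c("gamma_mean", "amplitude_norm")])
  ts <- structure(list(x = x, y = rows$label, subject_id = rows$subject_id,
                       center = stats::setNames(nums("center"), colnames(x)),
                       scale = stats::setNames(nums("scale"), colnames(x)),
                       threshold = nums("threshold")),
                  class = "swd_training_set")
  knn_fit(ts, as.integer(val("k")))
}
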