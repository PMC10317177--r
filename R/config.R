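#' Analysis configuration
#'
#' Bundles the tunable parameters of the detection pipeline.  Defaults are
#' the study settings: Morlet center frequency `fc = 1` Hz, analysis
#' pseudo-frequency `fa = 12` Hz (the pair maximizing the ictal-interictal
#' synchronization contrast), 1-s windows at 0.5-s step, the full `S19`
#' montage, a 30-s interictal reference for amplitude normalization, a k-NN
#' with 10 neighbours, a 1:3 ictal:interictal training ratio, and a
#' 95th-percentile interictal synchronization threshold for selecting ictal
#' training windows.
#'
#' @param fc Wavelet center frequency in Hz.
#' @param fa Analysis pseudo-frequency in Hz (`fa > fc`).
#' @param window_s Analysis window length in seconds.
#' @param step_s Window step in seconds (`0 < step_s <= window_s`).
#' @param subset_name Channel subset: `"S19"`, `"S12"`, `"S6"` or `"S4"`.
#' @param ref_window_s Length of the interictal amplitude-reference segment.
#' @param knn_k Number of k-NN neighbours.
#' @param class_ratio Interictal-to-ictal training-row ratio.
#' @param threshold_quantile Interictal synchronization quantile defining
#'   the ictal training-window threshold, in `(0, 1)`.
#' @param seed Integer master seed for all stochastic steps.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fc = 1, fa = 12, window_s = 1, step_s = 0.5,
                       subset_name = "S19", ref_window_s = 30,
                       knn_k = 10L, class_ratio = 3,
                       threshold_quantile = 0.95, seed = 1L) {
  stopifnot(fc > 0, fa > fc, window_s > 0,
            step_s > 0, step_s <= window_s,
            ref_window_s > 0, knn_k >= 1, class_ratio >= 1,
            threshold_quantile > 0, threshold_quantile < 1)
  subset_name <- match.arg(subset_name, c("S19", "S12", "S6", "S4"))
  structure(list(fc = fc, fa = fa, window_s = window_s, step_s = step_s,
                 subset_name = subset_name, ref_window_s = ref_window_s,
                 knn_k = as.integer(knn_k), class_ratio = class_ratio,
                 threshold_quantile = threshold_quantile,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a key-value text file
#'
#' One `key: value` pair per line (`#` starts a comment); keys are the
#' arguments of [run_config()].  Values given in `override` (e.g. parsed
#' command-line flags) take precedence over the file.
#'
#' @param path Config file path, or `NULL` for defaults only.
#' @param override Named list of values overriding the file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path = NULL, override = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(kv) < 2) stop("malformed config line: ", ln)
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      num <- suppressWarnings(as.numeric(val))
      vals[[key]] <- if (is.na(num)) val else num
    }
  }
  vals[names(override)] <- override
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
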