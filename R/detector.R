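#' Interictal synchronization threshold
#'
#' The empirical `q`-quantile (linear interpolation between order
#' statistics) of the interictal global synchronization values; at the
#' default `q = 0.95`, 95% of interictal windows have smaller mean gamma.
#' Ictal training windows must exceed this threshold.
#'
#' @param interictal_gammas Numeric vector of interictal `gamma_mean`
#'   values (at least 20).
#' @param q Quantile in `(0, 1)`.
#' @return The threshold (scalar).
#' @export
#' @examples
#' interictal_threshold((1:100) / 100)   # 0.9505
interictal_threshold <- function(interictal_gammas, q = 0.95) {
  interictal_gammas <- interictal_gammas[is.finite(interictal_gammas)]
  if (length(interictal_gammas) < 20)
    stop("need at least 20 interictal windows to estimate the threshold")
  stats::quantile(interictal_gammas, q, type = 7, names = FALSE)
}

#' Build a k-NN training set from cohort features
#'
#' Training rows follow the study's rules: ictal rows are the windows fully
#' embedded in seizures (taxonomy 3-5) whose global synchronization exceeds
#' the interictal threshold; windows partially overlapping seizures are
#' discarded; interictal rows are a seeded uniform random sample of
#' taxonomy-0 windows, `ratio` (default 3) per ictal row.  The held-out
#' subject, if any, is excluded entirely.  A feature scaler
#' (location/scale standardization) is fitted on the resulting rows.
#'
#' @param features Pooled feature table ([segment_features()] rows of
#'   several subjects) with columns `subject_id`, `taxonomy`, `gamma_mean`,
#'   `amplitude_norm`.
#' @param holdout Subject id to exclude, or `NULL`.
#' @param ratio Interictal rows per ictal row.
#' @param threshold_quantile Interictal quantile for the ictal gamma
#'   threshold.
#' @param seed Seed for the interictal subsample (or `NULL`).
#' @return List of class `swd_training_set`: `x` (matrix of scaled-feature
#'   inputs in original units), `y` (`"ictal"`/`"interictal"`),
#'   `subject_id`, `center`, `scale`, `threshold`.
#' @export
build_training_set <- function(features, holdout = NULL, ratio = 3,
                               threshold_quantile = 0.95, seed = NULL) {
  pool <- features
  if (!is.null(holdout)) pool <- pool[pool$subject_id != holdout, , drop = FALSE]
  if (nrow(pool) == 0L) stop("no training subjects left after holdout")
  inter <- pool[pool$taxonomy == 0L, , drop = FALSE]
  thr <- interictal_threshold(inter$gamma_mean, threshold_quantile)
  ict <- pool[pool$taxonomy %in% 3:5 & pool$gamma_mean > thr, , drop = FALSE]
  if (nrow(ict) == 0L)
    stop("no fully embedded ictal windows exceed the synchronization threshold")
  n_int <- round(ratio * nrow(ict))
  if (nrow(inter) < n_int) {
    warning("fewer interictal windows than ", ratio,
            "x ictal; using all of them")
    samp <- inter
  } else {
    idx <- with_seed(seed, sample.int(nrow(inter), n_int))
    samp <- inter[idx, , drop = FALSE]
  }
  rows <- rbind(ict, samp)
  x <- as.matrix(rows[, c("gamma_mean", "amplitude_norm")])
  y <- rep(c("ictal", "interictal"), c(nrow(ict), nrow(samp)))
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  structure(list(x = x, y = y, subject_id = rows$subject_id,
                 center = center, scale = scl, threshold = thr),
            class = "swd_training_set")
}

#' Fit and apply the k-NN seizure classifier
#'
#' A plain k-nearest-neighbour vote (default 10 neighbours, Euclidean
#' distance on standardized features, no distance weighting).  A query is
#' classified ictal when more than half of its `k` nearest training rows
#' are ictal; vote ties are broken toward interictal, which favours fewer
#' false positives.  Neighbour ties in distance are resolved by training-row
#' order, making predictions deterministic.
#'
#' @param training_set A [build_training_set()] result.
#' @param k Number of neighbours (`k <=` number of training rows).
#' @return `knn_fit()` returns an object of class `swd_knn`;
#'   `predict(model, newdata)` returns a character vector of
#'   `"ictal"`/`"interictal"` decisions.
#' @export
knn_fit <- function(training_set, k = 10L) {
  stopifnot(inherits(training_set, "swd_training_set"))
  k <- as.integer(k)
  if (k > nrow(training_set$x))
    stop("k exceeds the number of training rows")
  structure(list(ts = training_set, k = k), class = "swd_knn")
}

#' @rdname knn_fit
#' @param object An `swd_knn` model.
#' @param newdata Data frame or matrix with columns `gamma_mean` and
#'   `amplitude_norm`.
#' @param ... Unused.
#' @export
predict.swd_knn <- function(object, newdata, ...) {
  ts <- object$ts
  q <- as.matrix(as.data.frame(newdata)[, c("gamma_mean", "amplitude_norm")])
  if (!all(is.finite(q))) stop("query features must be finite")
  Xs <- sweep(sweep(ts$x, 2, ts$center), 2, ts$scale, "/")
  Qs <- sweep(sweep(q, 2, ts$center), 2, ts$scale, "/")
  # squared Euclidean distances, queries x training rows
  d2 <- outer(rowSums(Qs^2), rowSums(Xs^2), "+") - 2 * Qs %*% t(Xs)
  k <- object$k
  is_ict <- ts$y == "ictal"
  votes <- apply(d2, 1, function(r) sum(is_ict[order(r)[seq_len(k)]]))
  ifelse(votes > k / 2, "ictal", "interictal")
}

#' Remove isolated ictal windows
#'
#' Post-processing of the per-window decisions: any ictal window whose
#' previous and next windows are both non-ictal is relabelled interictal.
#' Consequently the shortest ictal interval that can survive is two
#' consecutive windows, i.e. 1.5 s at the default 1-s/0.5-s windowing.
#' The operation never creates ictal windows and is idempotent.
#'
#' @param decisions Character (`"ictal"`/`"interictal"`) or logical vector
#'   of window decisions ordered by window start.
#' @return Vector of the same type with isolated ictal windows cleared.
#' @export
#' @examples
#' postprocess_decisions(c("interictal", "ictal", "interictal"))
postprocess_decisions <- function(decisions) {
  lg <- if (is.logical(decisions)) decisions else decisions == "ictal"
  n <- length(lg)
  if (n == 0L) return(decisions)
  prev <- c(FALSE, lg[-n])
  nxt <- c(lg[-1], FALSE)
  iso <- lg & !prev & !nxt
  lg[iso] <- FALSE
  if (is.logical(decisions)) lg else ifelse(lg, "ictal", "interictal")
}

#' Leave-one-subject-out cross-validated detection
#'
#' One fold per subject: a k-NN model is built from the features of all
#' other subjects ([build_training_set()], [knn_fit()]) and applied to every
#' window of the held-out subject.  Optionally the isolated-window
#' post-processing is applied.  Per-fold interictal subsampling uses a seed
#' derived from `config$seed` and the fold index, so the whole procedure is
#' reproducible.
#'
#' @param features Pooled feature table for the cohort (all subjects).
#' @param annotations Pooled [annotation_set()] for the cohort.
#' @param durations Named numeric vector of recording durations in seconds,
#'   names = subject ids.
#' @param config A [run_config()].
#' @param postprocess Apply [postprocess_decisions()] to each fold's
#'   decisions (default `TRUE`).
#' @return List of class `swd_loocv`: `decisions` (data frame: subject_id,
#'   start, end, taxonomy, decision_raw, decision), `metrics` (per-subject
#'   [subject_metrics()] rows), `thresholds` (per-fold interictal
#'   thresholds).
#' @export
loocv <- function(features, annotations, durations, config = run_config(),
                  postprocess = TRUE) {
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2) stop("LOOCV needs at least two subjects")
  seeds <- derive_seeds(config$seed, length(subjects))
  dec_list <- vector("list", length(subjects))
  met_list <- vector("list", length(subjects))
  thr <- numeric(length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    ts <- build_training_set(features, holdout = s,
                             ratio = config$class_ratio,
                             threshold_quantile = config$threshold_quantile,
                             seed = seeds[i])
    model <- knn_fit(ts, config$knn_k)
    test <- features[features$subject_id == s, , drop = FALSE]
    test <- test[order(test$start), , drop = FALSE]
    raw <- predict(model, test)
    final <- if (postprocess) postprocess_decisions(raw) else raw
    dec_list[[i]] <- data.frame(subject_id = s, start = test$start,
                                end = test$end, taxonomy = test$taxonomy,
                                decision_raw = raw, decision = final,
                                stringsAsFactors = FALSE)
    met_list[[i]] <- subject_metrics(test, final, annotations, durations[[s]],
                                     config)
    thr[i] <- ts$threshold
  }
  structure(list(decisions = do.call(rbind, dec_list),
                 metrics = do.call(rbind, met_list),
                 thresholds = stats::setNames(thr, subjects)),
            class = "swd_loocv")
}
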