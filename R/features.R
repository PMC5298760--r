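#' Statistical and physical features of a candidate series
#'
#' Computes the nine descriptors used for significant-change spotting on a
#' candidate's dominant-axis samples: six statistical features (maximum,
#' minimum, mean, population standard deviation, root-mean-square, range) and
#' three physical features describing movement quality (movement time in
#' seconds, peak number, jerk metric).
#'
#' Peak number counts strict `+` to `-` sign changes of the first difference;
#' runs of equal samples (zero differences) are compressed first, so a
#' plateau counts as a single peak at its entry. The jerk metric is the RMS
#' of the first difference times the sample rate (RMS jerk, g/s), normalised
#' by the series range so it measures smoothness independently of amplitude;
#' it is defined as 0 for constant series.
#'
#' @param series numeric vector of dominant-axis samples (length >= 2).
#' @param sample_rate sampling rate in Hz.
#' @return A one-row data frame with columns `maximum`, `minimum`, `mean`,
#'   `std`, `rms`, `range`, `movement_time`, `peak_number`, `jerk_metric`.
#' @export
extract_features <- function(series, sample_rate) {
  n <- length(series)
  if (n < 2L) stop("degenerate candidate: feature extraction needs >= 2 samples")
  stopifnot(sample_rate > 0)
  mx <- max(series); mn <- min(series); mu <- mean(series)
  std <- sqrt(mean((series - mu)^2))  # population convention: rms^2 = std^2 + mean^2
  rms <- sqrt(mean(series^2))
  rng <- mx - mn
  d <- diff(series)
  s <- sign(d)
  s <- s[s != 0]
  peaks <- if (length(s) < 2L) 0L else sum(s[-length(s)] > 0 & s[-1L] < 0)
  jerk <- if (rng > 0) sqrt(mean(d^2)) * sample_rate / rng else 0
  data.frame(maximum = mx, minimum = mn, mean = mu, std = std, rms = rms,
             range = rng, movement_time = n / sample_rate,
             peak_number = as.integer(peaks), jerk_metric = jerk)
}

#' Names of the nine candidate features
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c("maximum", "minimum", "mean", "std", "rms", "range",
    "movement_time", "peak_number", "jerk_metric")
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection for one dominant axis: starting from the empty
#' set, repeatedly add the feature that maximises the inner
#' stratified-5-fold cross-validated F1 of the given classifier on the
#' already-selected set, and stop when no remaining feature strictly improves
#' the score or `max_features` is reached. Deterministic for a fixed `seed`
#' (which fixes the inner fold assignment).
#'
#' @param X data frame or matrix of feature columns (rows = candidates).
#' @param y logical or factor labels (significant vs not); both classes must
#'   be present.
#' @param axis axis tag attached to the result (`"X"`, `"Y"`, `"Z"` or
#'   `"pooled"`).
#' @param classifier_kind one of `"NB"`, `"kNN"`, `"SVM"`.
#' @param max_features cap on the number of selected features (default: all).
#' @param seed integer seed for the inner fold assignment.
#' @param n_folds inner cross-validation folds (default 5).
#' @return A list of class `sigspot_selection` with `axis`,
#'   `ranked_features` (ordered names) and `score_trace` (inner-CV F1 after
#'   each accepted feature).
#' @export
sequential_forward_selection <- function(X, y, axis = "pooled",
                                         classifier_kind = c("SVM", "kNN", "NB"),
                                         max_features = ncol(X), seed = 1L,
                                         n_folds = 5L) {
  classifier_kind <- match.arg(classifier_kind)
  X <- as.data.frame(X)
  y <- as.logical(y)
  if (length(unique(y)) < 2L)
    stop("sequential forward selection needs both classes present")
  if (nrow(X) < 10L)
    stop("sequential forward selection needs at least 10 rows")
  folds <- stratified_folds(y, k = n_folds, seed = seed)
  selected <- character(0)
  trace <- numeric(0)
  best_score <- -Inf
  remaining <- names(X)
  while (length(selected) < max_features && length(remaining) > 0L) {
    scores <- vapply(remaining, function(f) {
      cv_f1(X[, c(selected, f), drop = FALSE], y, classifier_kind, folds, seed)
    }, numeric(1))
    top <- which.max(scores)
    if (scores[top] <= best_score) break  # no strict improvement
    best_score <- unname(scores[top])
    selected <- c(selected, remaining[top])
    trace <- c(trace, best_score)
    remaining <- remaining[-top]
  }
  structure(list(axis = axis, ranked_features = selected, score_trace = trace),
            class = "sigspot_selection")
}

# Stratified k-fold assignment: within each class, rows are dealt to folds in
# a seeded random order. Returns an integer vector of fold ids per row.
stratified_folds <- function(y, k = 5L, seed = 1L) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Pooled-confusion F1 of one classifier over precomputed CV folds.
cv_f1 <- function(X, y, classifier_kind, folds, seed) {
  tp <- fp <- fn <- 0L
  for (f in sort(unique(folds))) {
    test <- folds == f
    if (!any(test) || length(unique(y[!test])) < 1L) next
    fit <- fit_classifier(classifier_kind, X[!test, , drop = FALSE], y[!test],
                          seed = seed)
    pred <- predict_classifier(fit, X[test, , drop = FALSE])
    tp <- tp + sum(pred & y[test])
    fp <- fp + sum(pred & !y[test])
    fn <- fn + sum(!pred & y[test])
  }
  if (tp == 0L) return(0)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}
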