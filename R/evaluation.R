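#' Event-matched comparison of spotted and ground-truth intervals
#'
#' Spotted and truth intervals are matched one-to-one greedily by descending
#' Jaccard overlap; pairs below `min_overlap` stay unmatched. Matched pairs
#' are true positives, unmatched spotted intervals false positives and
#' unmatched truth intervals false negatives, so `tp + fp` equals the number
#' of spotted intervals and `tp + fn` the number of truth intervals.
#'
#' @param spotted data frame (or 2-column matrix) of spotted significant
#'   intervals with columns `global_start`, `global_end` (half-open).
#' @param truth data frame of truth intervals with columns `start_sample`,
#'   `end_sample` (an [annotations()] object works; only significant rows
#'   should be passed) or `global_start`/`global_end`.
#' @param min_overlap Jaccard threshold for a match (default 0.5).
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
match_events <- function(spotted, truth, min_overlap = 0.5) {
  as_iv <- function(x) {
    if (is.matrix(x)) return(list(start = x[, 1L], end = x[, 2L]))
    if (all(c("global_start", "global_end") %in% names(x)))
      return(list(start = x$global_start, end = x$global_end))
    if (all(c("start_sample", "end_sample") %in% names(x)))
      return(list(start = x$start_sample, end = x$end_sample))
    stop("cannot interpret intervals")
  }
  s <- as_iv(spotted); t <- as_iv(truth)
  ns <- length(s$start); nt <- length(t$start)
  if (ns == 0L || nt == 0L)
    return(c(tp = 0L, fp = ns, fn = nt))
  J <- outer(seq_len(ns), seq_len(nt), function(i, j)
    interval_jaccard(s$start[i], s$end[i], t$start[j], t$end[j]))
  pairs <- which(J >= min_overlap, arr.ind = TRUE)
  tp <- 0L
  if (nrow(pairs) > 0L) {
    ord <- order(-J[pairs], pairs[, 2L], pairs[, 1L])
    pairs <- pairs[ord, , drop = FALSE]
    used_s <- logical(ns); used_t <- logical(nt)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      if (!used_s[i] && !used_t[j]) {
        used_s[i] <- TRUE; used_t[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  c(tp = tp, fp = ns - tp, fn = nt - tp)
}

#' Recall, precision and F1 from event counts
#'
#' `recall = tp / (tp + fn)`, `precision = tp / (tp + fp)`, F1 their harmonic
#' mean. Any metric with a zero denominator is defined as 0; the all-empty
#' triple (0, 0, 0) scores 0 on all three and is flagged with `empty = TRUE`.
#'
#' @param tp,fp,fn non-negative counts.
#' @return A one-row data frame with columns `tp`, `fp`, `fn`, `recall`,
#'   `precision`, `f1`, `empty`.
#' @export
compute_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  data.frame(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
             recall = recall, precision = precision, f1 = f1,
             empty = (tp + fp + fn) == 0L)
}

# Precompute labelled candidate-feature tables for a list of sessions at one
# boundary setting. Sessions: list of lists with $recording and $truth.
# `frames` optionally carries pre-filtered recordings + frames (one list per
# session with $filtered and $frames) so a grid sweep filters only once.
session_tables <- function(sessions, params, config = list(),
                           min_overlap = 0.5, frames = NULL) {
  if (is.null(frames)) frames <- session_frames(sessions, config)
  Map(function(s, fr) {
    merged <- merge_candidates(lapply(fr$frames, search_candidates,
                                      params = params,
                                      tail_fraction = fr$tail_fraction))
    rows <- candidate_feature_table(fr$filtered, merged)
    list(rows = label_candidates(rows, s$truth, min_overlap),
         truth = s$truth)
  }, sessions, frames)
}

# Filter + frame every session once (boundary parameters play no role here).
session_frames <- function(sessions, config = list()) {
  cfg <- utils::modifyList(list(low_hz = 0.1, high_hz = 12, filter_order = 3L,
                                causal = FALSE, window_seconds = 4,
                                overlap_fraction = 0.5, tail_fraction = 0.1),
                           config)
  lapply(sessions, function(s) {
    filt <- bandpass_filter(s$recording, cfg$low_hz, cfg$high_hz,
                            cfg$filter_order, causal = cfg$causal)
    list(filtered = filt,
         frames = make_frames(filt, cfg$window_seconds, cfg$overlap_fraction),
         tail_fraction = cfg$tail_fraction)
  })
}

# One LOOCV pass over precomputed tables.
loocv_tables <- function(tables, classifier_kind, seed = 1L,
                         min_overlap = 0.5, hyper = list()) {
  k <- length(tables)
  fold_rows <- vector("list", k)
  counts <- matrix(0L, nrow = k, ncol = 3L,
                   dimnames = list(NULL, c("tp", "fp", "fn")))
  for (i in seq_len(k)) {
    train <- do.call(rbind, lapply(tables[-i], `[[`, "rows"))
    train <- train[order(train$session_id, train$global_start), , drop = FALSE]
    selection <- list()
    for (ax in c(sort(unique(train$axis)), "pooled")) {
      sub <- if (ax == "pooled") train else train[train$axis == ax, , drop = FALSE]
      selection[[ax]] <- safe_sfs(sub[, feature_names(), drop = FALSE],
                                  sub$label, ax, classifier_kind, seed)
    }
    model <- train_spotter(train, classifier_kind, selection = selection,
                           seed = seed, hyper = hyper)
    seg <- spot(model, tables[[i]]$rows)
    pos <- seg$spotted[seg$spotted$decision, , drop = FALSE]
    tr <- tables[[i]]$truth
    counts[i, ] <- match_events(pos, tr[tr$is_significant, , drop = FALSE],
                                min_overlap)
    fold_rows[[i]] <- compute_metrics(counts[i, 1L], counts[i, 2L], counts[i, 3L])
  }
  folds <- do.call(rbind, fold_rows)
  folds <- cbind(session_id = vapply(tables, function(t)
    as.character(t$truth$session_id[1L]), character(1)), folds)
  rownames(folds) <- NULL
  pooled <- compute_metrics(sum(counts[, 1L]), sum(counts[, 2L]), sum(counts[, 3L]))
  list(folds = folds, pooled = pooled)
}

#' Leave-one-session-out cross-validation of the spotting pipeline
#'
#' Sessions (recording days) are the cross-validation unit: each fold holds
#' one session out, runs candidate search everywhere, performs per-axis
#' sequential forward selection and classifier training on the training
#' sessions only, then spots and event-matches the held-out session.
#' True/false positive/negative counts are pooled over folds before the
#' pooled metrics are computed.
#'
#' @param sessions list of sessions; each a list with `recording` (a
#'   [recording()]) and `truth` (an [annotations()] object). The output of
#'   [generate_dataset()] fits directly.
#' @param classifier_kind `"NB"`, `"kNN"` or `"SVM"`.
#' @param params [boundary_params()].
#' @param seed integer seed (inner CV folds and classifier fitting).
#' @param config pipeline configuration, see [search_session()].
#' @param min_overlap Jaccard threshold for labelling and event matching.
#' @param hyper classifier hyperparameters, see [train_spotter()].
#' @return List with `folds` (per-fold metric data frame, one row per
#'   held-out session) and `pooled` (metrics from summed counts).
#' @export
loocv <- function(sessions, classifier_kind = c("SVM", "kNN", "NB"),
                  params = boundary_params(), seed = 1L, config = list(),
                  min_overlap = 0.5, hyper = list()) {
  classifier_kind <- match.arg(classifier_kind)
  if (length(sessions) < 2L) stop("LOOCV needs at least 2 sessions")
  tables <- session_tables(sessions, params, config, min_overlap)
  loocv_tables(tables, classifier_kind, seed, min_overlap, hyper)
}

#' Boundary-parameter grid sweep with area aggregation
#'
#' Runs [loocv()] for every `(alpha_upper, alpha_lower)` cell of the grid and
#' every classifier, then aggregates cells into areas: the grid is
#' partitioned into 5x5 blocks labelled `A1`, `A2`, ... in row-major order
#' (rows = `alpha_upper` blocks), so the default 15x15 grid yields nine
#' areas of 25 cells each. Per area and classifier the mean and standard
#' deviation of each pooled metric over the area's cells are reported, plus
#' a per-area summary across classifiers.
#'
#' @param sessions as in [loocv()].
#' @param classifier_kinds character vector of classifiers to sweep.
#' @param grid_upper,grid_lower integer vectors of boundary values
#'   (defaults `1:15`); lengths must be multiples of the block size.
#' @param seed,config,min_overlap as in [loocv()].
#' @param block area block size (default 5).
#' @return List with `cells` (one row per cell x classifier with pooled
#'   counts and metrics), `areas` (per area x classifier mean/sd of each
#'   metric) and `areas_overall` (per area mean/sd across classifiers of the
#'   per-classifier area means).
#' @export
boundary_sweep <- function(sessions, classifier_kinds = c("kNN", "SVM", "NB"),
                           grid_upper = 1:15, grid_lower = 1:15, seed = 1L,
                           config = list(), min_overlap = 0.5, block = 5L) {
  if (length(grid_upper) %% block != 0L || length(grid_lower) %% block != 0L)
    stop("grid lengths must be multiples of the area block size")
  n_lower_blocks <- length(grid_lower) %/% block
  frames <- session_frames(sessions, config)
  cells <- list()
  for (ui in seq_along(grid_upper)) {
    for (li in seq_along(grid_lower)) {
      params <- boundary_params(grid_upper[ui], grid_lower[li])
      tables <- session_tables(sessions, params, config, min_overlap,
                               frames = frames)
      area_id <- ((ui - 1L) %/% block) * n_lower_blocks + (li - 1L) %/% block + 1L
      for (cl in classifier_kinds) {
        res <- loocv_tables(tables, cl, seed, min_overlap)
        cells[[length(cells) + 1L]] <-
          cbind(data.frame(alpha_upper = grid_upper[ui],
                           alpha_lower = grid_lower[li],
                           area = sprintf("A%d", area_id),
                           classifier = cl, stringsAsFactors = FALSE),
                res$pooled)
      }
    }
  }
  cells <- do.call(rbind, cells)
  agg <- function(df, by) {
    out <- list()
    for (m in c("recall", "precision", "f1")) {
      mu <- stats::aggregate(df[[m]], df[by], mean)
      sd <- stats::aggregate(df[[m]], df[by], function(v)
        if (length(v) > 1L) stats::sd(v) else 0)
      names(mu)[ncol(mu)] <- paste0(m, "_mean")
      names(sd)[ncol(sd)] <- paste0(m, "_sd")
      out[[m]] <- merge(mu, sd, by = by)
    }
    Reduce(function(a, b) merge(a, b, by = by), out)
  }
  areas <- agg(cells, c("area", "classifier"))
  areas_overall <- agg(areas[, c("area",
                                 grep("_mean$", names(areas), value = TRUE))] |>
                         stats::setNames(c("area", "recall", "precision", "f1")),
                       "area")
  list(cells = cells, areas = areas, areas_overall = areas_overall)
}
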