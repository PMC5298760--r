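#' Jaccard overlap of half-open integer intervals
#'
#' @param a_start,a_end,b_start,b_end interval bounds (half-open, 0-based).
#'   `a_*` may be vectors; `b_*` scalar or equal-length.
#' @return Numeric vector of Jaccard indices (intersection / union).
#' @keywords internal
interval_jaccard <- function(a_start, a_end, b_start, b_end) {
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  union <- (a_end - a_start) + (b_end - b_start) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Build the feature table for a set of merged candidates
#'
#' Extracts each candidate's dominant-axis sub-series from the (filtered)
#' recording and computes its feature vector.
#'
#' @param rec the [recording()] the candidates were searched in (after
#'   filtering).
#' @param candidates a candidate data frame from [merge_candidates()] (or
#'   [search_candidates()]), with global coordinates.
#' @return The candidate data frame with `session_id` and the nine feature
#'   columns appended.
#' @export
candidate_feature_table <- function(rec, candidates) {
  stopifnot(inherits(rec, "sigspot_recording"))
  axcol <- c(X = 1L, Y = 2L, Z = 3L)
  feats <- lapply(seq_len(nrow(candidates)), function(i) {
    s <- rec$data[(candidates$global_start[i] + 1L):candidates$global_end[i],
                  axcol[[candidates$axis[i]]]]
    extract_features(s, rec$sample_rate_hz)
  })
  feats <- if (length(feats)) do.call(rbind, feats) else
    as.data.frame(stats::setNames(rep(list(numeric(0)), 9L), feature_names()))
  out <- cbind(session_id = rep(rec$session_id, nrow(candidates)),
               candidates, feats)
  rownames(out) <- NULL
  out
}

#' Label candidates against ground-truth annotations
#'
#' A candidate is labelled significant when its Jaccard overlap with some
#' ground-truth significant interval reaches `min_overlap`. One truth
#' interval may label several candidates (labelling is per candidate; the
#' one-to-one matching of [match_events()] is an evaluation concern only).
#'
#' @param candidates candidate (or candidate-feature) data frame with
#'   `global_start` / `global_end`.
#' @param truth a [annotations()] object for the same session.
#' @param min_overlap Jaccard threshold (default 0.5).
#' @return The input data frame with a logical `label` column appended.
#' @export
label_candidates <- function(candidates, truth, min_overlap = 0.5) {
  sig <- truth[truth$is_significant, , drop = FALSE]
  label <- vapply(seq_len(nrow(candidates)), function(i) {
    if (nrow(sig) == 0L) return(FALSE)
    j <- interval_jaccard(sig$start_sample, sig$end_sample,
                          candidates$global_start[i], candidates$global_end[i])
    max(j) >= min_overlap
  }, logical(1))
  candidates$label <- label
  candidates
}

# Run feature selection for one axis partition, degrading gracefully when the
# partition cannot support it (single class or too few rows): then all nine
# features are kept unranked.
safe_sfs <- function(X, y, axis, classifier_kind, seed) {
  if (length(unique(y)) < 2L || length(y) < 10L) {
    return(structure(list(axis = axis, ranked_features = names(X),
                          score_trace = numeric(0)),
                     class = "sigspot_selection"))
  }
  sequential_forward_selection(X, y, axis = axis,
                               classifier_kind = classifier_kind, seed = seed)
}

#' Train a significant-change spotting model
#'
#' Fits one classifier per dominant axis present in the training rows (falling
#' back to a pooled model for axes with a single-class partition) plus a
#' pooled model used for axes unseen at training time. Feature
#' standardisation parameters are fitted on training rows only, inside each
#' classifier fit.
#'
#' @param rows labelled candidate-feature rows (from
#'   [candidate_feature_table()] + [label_candidates()]): must contain
#'   `axis`, the nine feature columns and a logical `label`.
#' @param classifier_kind `"NB"`, `"kNN"` or `"SVM"`.
#' @param selection named list mapping axis (and optionally `"pooled"`) to
#'   [sequential_forward_selection()] results; `NULL` selects all nine
#'   features everywhere.
#' @param seed integer seed controlling classifier fitting.
#' @param hyper optional classifier hyperparameters (`k` for kNN; `cost`,
#'   `gamma` for the RBF SVM).
#' @param min_class_rows minimum training rows per class an axis partition
#'   must contain to earn its own fit (default 5, the kNN vote size: a
#'   partition with fewer members of a class than the vote size cannot
#'   out-vote the other class, and so few rows support no meaningful class
#'   model for any classifier kind). Sparser axes fall back to the pooled
#'   model.
#' @return An object of class `sigspot_model` with per-axis fits, the pooled
#'   fit, the feature sets used, and metadata (including single-class
#'   fallback warnings).
#' @export
train_spotter <- function(rows, classifier_kind = c("SVM", "kNN", "NB"),
                          selection = NULL, seed = 1L, hyper = list(),
                          min_class_rows = 5L) {
  classifier_kind <- match.arg(classifier_kind)
  stopifnot(all(c("axis", "label", feature_names()) %in% names(rows)))
  rows <- rows[order(rows$session_id, rows$global_start), , drop = FALSE]
  sel_for <- function(ax) {
    if (!is.null(selection) && !is.null(selection[[ax]]))
      selection[[ax]]$ranked_features
    else feature_names()
  }
  warnings <- character(0)
  per_axis <- list()
  for (ax in sort(unique(rows$axis))) {
    sub <- rows[rows$axis == ax, , drop = FALSE]
    if (length(unique(sub$label)) < 2L ||
        min(table(sub$label)) < min_class_rows) {
      warnings <- c(warnings, sprintf(
        "axis %s: single-class or sparse training partition; pooled model used", ax))
      next
    }
    feats <- sel_for(ax)
    per_axis[[ax]] <- list(
      features = feats,
      fit = fit_classifier(classifier_kind, sub[, feats, drop = FALSE],
                           sub$label, seed = seed, hyper = hyper))
  }
  pooled_feats <- sel_for("pooled")
  pooled <- list(features = pooled_feats,
                 fit = fit_classifier(classifier_kind,
                                      rows[, pooled_feats, drop = FALSE],
                                      rows$label, seed = seed, hyper = hyper))
  if (length(unique(rows$label)) < 2L)
    warnings <- c(warnings, "pooled training set is single-class; constant model")
  structure(list(classifier_kind = classifier_kind,
                 per_axis = per_axis, pooled = pooled,
                 selection = selection, seed = seed, hyper = hyper,
                 metadata = list(warnings = warnings,
                                 n_train = nrow(rows))),
            class = "sigspot_model")
}

#' @export
print.sigspot_model <- function(x, ...) {
  cat(sprintf("<sigspot_model> %s; per-axis fits: %s; trained on %d candidates\n",
              x$classifier_kind,
              if (length(x$per_axis)) paste(names(x$per_axis), collapse = ",")
              else "(pooled only)",
              x$metadata$n_train))
  for (w in x$metadata$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Classify candidates as significant or spurious
#'
#' Every merged candidate receives a binary decision from the model fitted
#' for its dominant axis (or the pooled model when no per-axis fit exists),
#' using that fit's feature subset and standardisation parameters.
#'
#' @param model a [train_spotter()] model.
#' @param rows candidate-feature rows for one session
#'   ([candidate_feature_table()] output).
#' @param session_id session identifier for the result (defaults to the rows'
#'   session).
#' @param params the [boundary_params()] used during the search, recorded in
#'   the result.
#' @return An object of class `sigspot_segmentation`: list with `session_id`,
#'   `params` and `spotted`, a data frame of all candidates (sorted by
#'   `global_start`) with columns `global_start`, `global_end`, `axis`,
#'   `decision` (logical) and `score`.
#' @export
spot <- function(model, rows, session_id = NULL, params = NULL) {
  stopifnot(inherits(model, "sigspot_model"))
  if (is.null(session_id))
    session_id <- if (nrow(rows) > 0L) as.character(rows$session_id[1L]) else ""
  decision <- logical(nrow(rows))
  score <- numeric(nrow(rows))
  for (ax in unique(rows$axis)) {
    idx <- which(rows$axis == ax)
    m <- if (!is.null(model$per_axis[[ax]])) model$per_axis[[ax]] else model$pooled
    pred <- predict_classifier(m$fit, rows[idx, m$features, drop = FALSE])
    decision[idx] <- as.logical(pred)
    score[idx] <- attr(pred, "score")
  }
  spotted <- data.frame(global_start = rows$global_start,
                        global_end = rows$global_end,
                        axis = rows$axis,
                        decision = decision, score = score,
                        stringsAsFactors = FALSE)
  spotted <- spotted[order(spotted$global_start, spotted$global_end), , drop = FALSE]
  rownames(spotted) <- NULL
  structure(list(session_id = session_id, spotted = spotted, params = params),
            class = "sigspot_segmentation")
}

#' @export
print.sigspot_segmentation <- function(x, ...) {
  cat(sprintf("<sigspot_segmentation> session '%s': %d candidates, %d spotted significant\n",
              x$session_id, nrow(x$spotted), sum(x$spotted$decision)))
  invisible(x)
}

#' Candidate search + feature extraction for one recording
#'
#' The pre-classifier half of the pipeline: band-pass filter, sliding frames,
#' per-frame candidate search, cross-frame merge, feature extraction.
#'
#' @param rec a raw [recording()].
#' @param params [boundary_params()].
#' @param config optional list overriding pipeline settings: `low_hz`,
#'   `high_hz`, `filter_order`, `causal`, `window_seconds`,
#'   `overlap_fraction`, `tail_fraction`.
#' @return List with `filtered` (the filtered recording) and `rows` (merged
#'   candidate-feature table).
#' @export
search_session <- function(rec, params = boundary_params(), config = list()) {
  cfg <- utils::modifyList(list(low_hz = 0.1, high_hz = 12, filter_order = 3L,
                                causal = FALSE, window_seconds = 4,
                                overlap_fraction = 0.5, tail_fraction = 0.1),
                           config)
  filt <- bandpass_filter(rec, cfg$low_hz, cfg$high_hz, cfg$filter_order,
                          causal = cfg$causal)
  frames <- make_frames(filt, cfg$window_seconds, cfg$overlap_fraction)
  merged <- merge_candidates(lapply(frames, search_candidates,
                                    params = params,
                                    tail_fraction = cfg$tail_fraction))
  list(filtered = filt, rows = candidate_feature_table(filt, merged))
}

#' Run the full segmentation pipeline on one recording
#'
#' Filter, frame, search, merge, extract features and classify, in that
#' order. Deterministic for fixed inputs, model and configuration.
#'
#' @inheritParams search_session
#' @param model a fitted [train_spotter()] model.
#' @return A `sigspot_segmentation` (see [spot()]).
#' @export
run_pipeline <- function(rec, model, params = boundary_params(),
                         config = list()) {
  sr <- search_session(rec, params, config)
  spot(model, sr$rows, session_id = rec$session_id, params = params)
}

#' Save / load a spotting model
#'
#' The archive is a list with a format version, the package version and the
#' model object, written with `saveRDS`.
#'
#' @param model a `sigspot_model`.
#' @param path file path for the archive.
#' @return `path` invisibly (`save_spotter`); the model (`load_spotter`).
#' @export
save_spotter <- function(model, path) {
  stopifnot(inherits(model, "sigspot_model"))
  saveRDS(list(format = 1L,
               package_version = as.character(utils::packageVersion("sigspot")),
               model = model), path)
  invisible(path)
}

#' @rdname save_spotter
#' @export
load_spotter <- function(path) {
  arc <- readRDS(path)
  if (!is.list(arc) || is.null(arc$format) || arc$format != 1L)
    stop("unrecognised model archive format")
  arc$model
}
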