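#' Boundary parameters for candidate extension
#'
#' `alpha_upper` bounds each step of the end-point search and `alpha_lower`
#' each step of the start-point search, both in samples. These are the two
#' hyperparameters swept by [boundary_sweep()]; the default pair (9, 12) is
#' the combination with the best overall F1 in the reference grid.
#'
#' @param alpha_upper,alpha_lower positive integers (samples).
#' @return An object of class `sigspot_boundary_params`.
#' @export
boundary_params <- function(alpha_upper = 9L, alpha_lower = 12L) {
  alpha_upper <- as.integer(alpha_upper)
  alpha_lower <- as.integer(alpha_lower)
  if (is.na(alpha_upper) || alpha_upper < 1L || is.na(alpha_lower) || alpha_lower < 1L)
    stop("alpha_upper and alpha_lower must be integers >= 1")
  structure(list(alpha_upper = alpha_upper, alpha_lower = alpha_lower),
            class = "sigspot_boundary_params")
}

#' Identify the dominant acceleration axis of a frame
#'
#' For each axis the spread is the difference between the average of the
#' largest `tail_fraction` of samples and the average of the smallest
#' `tail_fraction` (tail count `ceiling(tail_fraction * window_len)`, at
#' least 1). The axis with the largest spread dominates; ties are broken by
#' the fixed priority X > Y > Z.
#'
#' @param frame a `sigspot_frame` from [make_frames()].
#' @param tail_fraction fraction of samples averaged in each tail
#'   (default 0.1, i.e., the smallest/largest ten percent).
#' @return A list with `axis` (one of `"X"`, `"Y"`, `"Z"`) and
#'   `spread_per_axis` (named numeric vector of per-axis spreads in g).
#' @export
identify_dominant_axis <- function(frame, tail_fraction = 0.1) {
  stopifnot(inherits(frame, "sigspot_frame"))
  if (!(tail_fraction > 0 && tail_fraction <= 0.5))
    stop("tail_fraction must be in (0, 0.5]")
  w <- frame$window_len
  if (w < 2L) stop("frame must contain at least 2 samples")
  k <- max(1L, as.integer(ceiling(tail_fraction * w)))
  spread <- vapply(1:3, function(j) {
    s <- sort(frame$data[, j])
    mean(s[(w - k + 1L):w]) - mean(s[1:k])
  }, numeric(1))
  names(spread) <- c("X", "Y", "Z")
  axis <- names(spread)[which.max(spread)]  # which.max keeps X > Y > Z priority
  list(axis = axis, spread_per_axis = spread)
}

#' Event-detection threshold of a series
#'
#' The threshold for mean-crossing event detection is simply the arithmetic
#' mean of the frame's dominant-axis samples.
#'
#' @param series numeric vector.
#' @return The mean of `series`.
#' @export
compute_threshold <- function(series) {
  if (length(series) == 0L) stop("series must be non-empty")
  mean(series)
}

#' Detect ascending mean-crossing events
#'
#' An event is a pair of adjacent samples that straddles the threshold in
#' ascending order: `series[i] < threshold` and `series[i + 1] > threshold`,
#' both strict, so samples exactly at the threshold never trigger events and
#' descending crossings are ignored.
#'
#' @param series numeric vector (length >= 2).
#' @param threshold crossing threshold.
#' @return A data frame with one row per event, columns `i_low` and `i_high`
#'   (0-based indices into `series`, `i_high = i_low + 1`) and `threshold`,
#'   ordered by `i_low`.
#' @export
detect_events <- function(series, threshold) {
  n <- length(series)
  if (n < 2L) stop("series must have at least 2 samples")
  d <- series - threshold
  i <- which(d[-n] < 0 & d[-1L] > 0)  # 1-based position of the low sample
  data.frame(i_low = i - 1L, i_high = i, threshold = rep(threshold, length(i)))
}

#' Extend a candidate end point by recursive local-maximum search
#'
#' One extension step looks at the window from the current index to
#' `alpha_upper` samples to its right (clipped at the end of the series) and
#' jumps to the index of the window maximum; if the current index already
#' attains the maximum the search stops and the current index is returned.
#' Ties inside a window are broken towards the index closest to the current
#' point, which guarantees fixed points on constant runs. The current index
#' strictly increases on every recursion, so the search terminates within
#' `length(series)` steps.
#'
#' @param series numeric vector.
#' @param initial_end 0-based starting index (the upper sample of a
#'   mean-crossing event).
#' @param alpha_upper extension window size in samples (>= 1).
#' @return The 0-based index of the candidate end point (a fixed point of the
#'   extension map).
#' @export
extend_end <- function(series, initial_end, alpha_upper) {
  n <- length(series)
  stopifnot(initial_end >= 0, initial_end < n, alpha_upper >= 1)
  cur <- as.integer(initial_end)
  for (iter in seq_len(n + 1L)) {
    hi <- min(cur + as.integer(alpha_upper), n - 1L)
    win <- series[(cur + 1L):(hi + 1L)]
    nxt <- cur + which.max(win) - 1L  # which.max: first max = closest to cur
    if (nxt == cur) return(cur)
    cur <- nxt
  }
  stop("extend_end failed to terminate")  # unreachable: cur strictly increases
}

#' Extend a candidate start point by recursive local-minimum search
#'
#' Mirror of [extend_end()]: each step searches the window from
#' `alpha_lower` samples to the left of the current index (clipped at 0) up
#' to the current index for the minimum, jumping left until the current index
#' itself attains the window minimum. Ties are broken towards the index
#' closest to the current point.
#'
#' @param series numeric vector.
#' @param initial_start 0-based starting index (the lower sample of a
#'   mean-crossing event).
#' @param alpha_lower extension window size in samples (>= 1).
#' @return The 0-based index of the candidate start point.
#' @export
extend_start <- function(series, initial_start, alpha_lower) {
  n <- length(series)
  stopifnot(initial_start >= 0, initial_start < n, alpha_lower >= 1)
  cur <- as.integer(initial_start)
  for (iter in seq_len(n + 1L)) {
    lo <- max(cur - as.integer(alpha_lower), 0L)
    win <- series[(lo + 1L):(cur + 1L)]
    m <- which(win == min(win))
    nxt <- lo + m[length(m)] - 1L  # last min = closest to cur
    if (nxt == cur) return(cur)
    cur <- nxt
  }
  stop("extend_start failed to terminate")
}

#' Search one frame for candidate significant series
#'
#' The full per-frame hierarchical search: identify the dominant axis,
#' compute the mean threshold on it, detect ascending mean-crossing events,
#' and grow each event into a complete candidate with [extend_start()] (from
#' the event's lower sample) and [extend_end()] (from its upper sample).
#' Degenerate candidates with `start == end` are discarded. Extension windows
#' are clipped at the frame boundaries; duplicates re-detected by
#' overlapping frames are resolved later by [merge_candidates()].
#'
#' @param frame a `sigspot_frame`.
#' @param params a [boundary_params()] object.
#' @param tail_fraction passed to [identify_dominant_axis()].
#' @return A data frame of candidates, one row each, sorted by `start`:
#'   columns `frame_index`, `axis`, `start`, `end` (0-based frame-local
#'   indices of the boundary samples, inclusive), `i_low`, `i_high` (the seed
#'   event), `global_start`, `global_end` (0-based half-open recording
#'   coordinates, `global_end = frame offset + end + 1`).
#' @export
search_candidates <- function(frame, params = boundary_params(),
                              tail_fraction = 0.1) {
  stopifnot(inherits(frame, "sigspot_frame"),
            inherits(params, "sigspot_boundary_params"))
  dom <- identify_dominant_axis(frame, tail_fraction)
  series <- frame$data[, c(X = 1L, Y = 2L, Z = 3L)[[dom$axis]]]
  thr <- compute_threshold(series)
  ev <- detect_events(series, thr)
  if (nrow(ev) == 0L) return(empty_candidates())
  start <- vapply(ev$i_low, function(i) extend_start(series, i, params$alpha_lower),
                  integer(1))
  end <- vapply(ev$i_high, function(i) extend_end(series, i, params$alpha_upper),
                integer(1))
  keep <- start < end
  out <- data.frame(frame_index = rep(frame$frame_index, sum(keep)),
                    axis = rep(dom$axis, sum(keep)),
                    start = start[keep], end = end[keep],
                    i_low = ev$i_low[keep], i_high = ev$i_high[keep],
                    global_start = frame$global_start + start[keep],
                    global_end = frame$global_start + end[keep] + 1L,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

empty_candidates <- function() {
  data.frame(frame_index = integer(), axis = character(),
             start = integer(), end = integer(),
             i_low = integer(), i_high = integer(),
             global_start = integer(), global_end = integer(),
             stringsAsFactors = FALSE)
}

#' Merge candidates found in overlapping frames
#'
#' Frames overlap by 50%, so the same significant series is typically
#' re-detected in two consecutive frames (possibly clipped at a frame
#' boundary in one of them). Two candidates are duplicates when their global
#' intervals overlap by more than half the length of the shorter interval.
#' Among duplicates the longest interval is kept (ties broken by earliest
#' frame, then earliest start), so a boundary-clipped fragment never shadows
#' the complete detection from the neighbouring frame.
#'
#' @param per_frame a list of candidate data frames from
#'   [search_candidates()], or a single combined data frame.
#' @return A candidate data frame sorted by `global_start` in which every
#'   pair overlaps by at most half the shorter interval.
#' @export
merge_candidates <- function(per_frame) {
  all <- if (is.data.frame(per_frame)) per_frame else do.call(rbind, per_frame)
  if (is.null(all) || nrow(all) == 0L) return(empty_candidates())
  len <- all$global_end - all$global_start
  ord <- order(-len, all$frame_index, all$global_start)
  all <- all[ord, , drop = FALSE]
  len <- len[ord]
  keep <- logical(nrow(all))
  for (i in seq_len(nrow(all))) {
    ks <- which(keep)
    if (length(ks) > 0L) {
      ov <- pmin(all$global_end[ks], all$global_end[i]) -
        pmax(all$global_start[ks], all$global_start[i])
      shorter <- pmin(len[ks], len[i])
      if (any(ov > 0.5 * shorter)) next
    }
    keep[i] <- TRUE
  }
  out <- all[keep, , drop = FALSE]
  out <- out[order(out$global_start, out$global_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
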