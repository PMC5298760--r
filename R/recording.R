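#' Construct a triaxial accelerometer recording
#'
#' A recording holds one session's continuous triaxial acceleration stream
#' (in g) together with its sample rate and provenance metadata. Acceleration
#' is stored as an n x 3 matrix with columns `x`, `y`, `z`.
#'
#' @param data numeric matrix or data frame with three columns (x, y, z
#'   acceleration in g).
#' @param sample_rate_hz sampling rate in Hz (default 40).
#' @param session_id character session identifier.
#' @param task_label character task label (e.g., one of the cleaning tasks, or
#'   a synthetic label).
#' @param sensor_range_g absolute sensor range in g used for validation of raw
#'   data (default 6). Set to `Inf` to skip the range check (e.g., for
#'   filtered signals).
#' @return An object of class `sigspot_recording` with elements `session_id`,
#'   `task_label`, `sample_rate_hz`, `data` (n x 3 matrix) and `n_samples`.
#' @export
recording <- function(data, sample_rate_hz = 40, session_id = "session",
                      task_label = "unknown", sensor_range_g = 6) {
  data <- as.matrix(data)
  if (ncol(data) != 3L)
    stop("recording data must have exactly 3 columns (x, y, z)")
  storage.mode(data) <- "double"
  colnames(data) <- c("x", "y", "z")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be a positive number")
  if (nrow(data) > 0L) {
    if (any(!is.finite(data)))
      stop("recording contains non-finite acceleration values")
    if (is.finite(sensor_range_g) && any(abs(data) > sensor_range_g))
      stop(sprintf("acceleration exceeds sensor range of %g g", sensor_range_g))
  }
  structure(
    list(session_id = as.character(session_id),
         task_label = as.character(task_label),
         sample_rate_hz = as.numeric(sample_rate_hz),
         data = data,
         n_samples = nrow(data)),
    class = "sigspot_recording")
}

#' @export
print.sigspot_recording <- function(x, ...) {
  cat(sprintf("<sigspot_recording> session '%s' (%s)\n", x$session_id, x$task_label))
  cat(sprintf("  %d samples @ %g Hz (%.1f s)\n",
              x$n_samples, x$sample_rate_hz, x$n_samples / x$sample_rate_hz))
  invisible(x)
}

#' Read a recording from CSV
#'
#' Accepts rows of `time_s,x_g,y_g,z_g` or `x_g,y_g,z_g`; a header line is
#' auto-detected. Timestamps, when present, are validated as strictly
#' increasing but not otherwise used (the nominal sample rate governs all
#' timing).
#'
#' @param path path to a CSV file.
#' @param sample_rate sampling rate in Hz to attach to the recording.
#' @param session_id,task_label metadata to attach; `session_id` defaults to
#'   the file name without extension.
#' @param sensor_range_g validation range in g, see [recording()].
#' @return A [recording()] object.
#' @export
read_recording <- function(path, sample_rate = 40, session_id = NULL,
                           task_label = "unknown", sensor_range_g = 6) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("parse error in %s: file is empty", path))
  first <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  data_lines <- if (has_header) lines[-1L] else lines
  offset <- if (has_header) 1L else 0L
  if (length(data_lines) == 0L)
    stop(sprintf("parse error in %s: no data rows", path))
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != ncols[1L])) {
    bad <- which(ncols != ncols[1L])[1L]
    stop(sprintf("parse error in %s at line %d: expected %d fields, got %d",
                 path, bad + offset, ncols[1L], ncols[bad]))
  }
  if (!ncols[1L] %in% c(3L, 4L))
    stop(sprintf("parse error in %s: rows must have 3 (x,y,z) or 4 (t,x,y,z) fields", path))
  vals <- suppressWarnings(matrix(as.numeric(unlist(parts)),
                                  ncol = ncols[1L], byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1L, anyNA))[1L]
    stop(sprintf("parse error in %s at line %d: non-numeric value",
                 path, bad + offset))
  }
  if (ncols[1L] == 4L) {
    ts <- vals[, 1L]
    if (length(ts) > 1L && any(diff(ts) <= 0))
      stop(sprintf("validation error in %s: timestamps are not strictly increasing", path))
    vals <- vals[, -1L, drop = FALSE]
  }
  if (is.null(session_id))
    session_id <- sub("\\.[^.]*$", "", basename(path))
  recording(vals, sample_rate_hz = sample_rate, session_id = session_id,
            task_label = task_label, sensor_range_g = sensor_range_g)
}

#' Write a recording to CSV
#'
#' Writes header `time_s,x_g,y_g,z_g` with timestamps derived from the sample
#' rate. Values are written at full double precision so that
#' [read_recording()] round-trips exactly.
#'
#' @param rec a [recording()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sigspot_recording"))
  t <- (seq_len(rec$n_samples) - 1L) / rec$sample_rate_hz
  rows <- sprintf("%.17g,%.17g,%.17g,%.17g",
                  t, rec$data[, 1L], rec$data[, 2L], rec$data[, 3L])
  writeLines(c("time_s,x_g,y_g,z_g", rows), path)
  invisible(path)
}

#' Construct an annotation set of ground-truth intervals
#'
#' Intervals are half-open `[start_sample, end_sample)` in 0-based sample
#' coordinates of the matching recording. Significant intervals must be
#' pairwise non-overlapping.
#'
#' @param session_id session identifier matching the recording.
#' @param start_sample,end_sample integer vectors of interval bounds
#'   (0-based, half-open).
#' @param is_significant logical vector flagging true significant series.
#' @param n_samples optional recording length for bounds validation.
#' @return An object of class `sigspot_annotations`: a data frame with columns
#'   `session_id`, `start_sample`, `end_sample`, `is_significant`, sorted by
#'   `start_sample`.
#' @export
annotations <- function(session_id, start_sample, end_sample,
                        is_significant = TRUE, n_samples = NULL) {
  n <- length(start_sample)
  df <- data.frame(session_id = rep_len(as.character(session_id), n),
                   start_sample = as.integer(start_sample),
                   end_sample = as.integer(end_sample),
                   is_significant = rep_len(as.logical(is_significant), n))
  if (n > 0L) {
    if (any(df$start_sample < 0L) || any(df$start_sample >= df$end_sample))
      stop("annotation intervals must satisfy 0 <= start_sample < end_sample")
    if (!is.null(n_samples) && any(df$end_sample > n_samples))
      stop("annotation interval extends past the end of the recording")
    df <- df[order(df$start_sample, df$end_sample), , drop = FALSE]
    sig <- df[df$is_significant, , drop = FALSE]
    if (nrow(sig) > 1L &&
        any(sig$start_sample[-1L] < sig$end_sample[-nrow(sig)]))
      stop("significant annotation intervals must not overlap")
    rownames(df) <- NULL
  }
  class(df) <- c("sigspot_annotations", "data.frame")
  df
}

#' Read annotations from CSV
#'
#' Expects columns `session_id,start_sample,end_sample,is_significant`.
#'
#' @param path path to a CSV file.
#' @param n_samples optional recording length for validation.
#' @return A [annotations()] object.
#' @export
read_annotations <- function(path, n_samples = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("session_id", "start_sample", "end_sample", "is_significant")
  if (!all(req %in% names(df)))
    stop(sprintf("annotation file %s must have columns %s",
                 path, paste(req, collapse = ",")))
  annotations(df$session_id, df$start_sample, df$end_sample,
              as.logical(df$is_significant), n_samples = n_samples)
}

#' Write annotations to CSV
#' @param ann a [annotations()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
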