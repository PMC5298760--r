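#' Partition a recording into overlapping sliding frames
#'
#' The stream is divided into fixed-length windows (default four seconds with
#' 50% overlap, long enough to cover at least one complete motion since a
#' single periodic gesture does not exceed two seconds). Window length in
#' samples is `round(window_seconds * sample_rate)`; the stride is
#' `floor(window_len * (1 - overlap_fraction))`. Trailing samples that do not
#' fill a frame are dropped, so the number of frames is
#' `floor((n_samples - window_len) / stride) + 1` when `n_samples >=
#' window_len` and 0 otherwise.
#'
#' @param rec a [recording()] object.
#' @param window_seconds window length in seconds (default 4).
#' @param overlap_fraction fractional overlap between consecutive frames in
#'   `[0, 1)` (default 0.5).
#' @return A list of frames, each of class `sigspot_frame` with elements
#'   `frame_index` (1-based), `global_start` (0-based sample offset into the
#'   recording), `window_len`, `sample_rate_hz` and `data` (window_len x 3
#'   matrix).
#' @export
make_frames <- function(rec, window_seconds = 4, overlap_fraction = 0.5) {
  stopifnot(inherits(rec, "sigspot_recording"))
  window_len <- as.integer(round(window_seconds * rec$sample_rate_hz))
  if (window_len < 2L)
    stop("window_seconds * sample_rate must be at least 2 samples")
  if (!(overlap_fraction >= 0 && overlap_fraction < 1))
    stop("overlap_fraction must be in [0, 1)")
  stride <- as.integer(floor(window_len * (1 - overlap_fraction)))
  if (stride < 1L) stop("stride must be at least 1 sample")
  n <- rec$n_samples
  if (n < window_len) return(list())
  n_frames <- (n - window_len) %/% stride + 1L
  lapply(seq_len(n_frames), function(i) {
    g0 <- (i - 1L) * stride
    structure(
      list(frame_index = i,
           global_start = g0,
           window_len = window_len,
           sample_rate_hz = rec$sample_rate_hz,
           data = rec$data[(g0 + 1L):(g0 + window_len), , drop = FALSE]),
      class = "sigspot_frame")
  })
}

#' @export
print.sigspot_frame <- function(x, ...) {
  cat(sprintf("<sigspot_frame> #%d, samples [%d, %d) @ %g Hz\n",
              x$frame_index, x$global_start, x$global_start + x$window_len,
              x$sample_rate_hz))
  invisible(x)
}
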