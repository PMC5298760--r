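#' Band-pass filter a recording
#'
#' Applies a Butterworth band-pass (default third order, 0.1--12 Hz, the
#' standard artefact-removal band for wrist-worn accelerometry at 40 Hz) to
#' each axis independently. By default the filter is applied forward and
#' backward (zero phase) so that event indices found downstream are not
#' shifted by group delay; `causal = TRUE` gives a single forward pass for
#' streaming parity.
#'
#' @param rec a [recording()] object.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < sample_rate / 2`.
#' @param order filter order per band edge (default 3).
#' @param causal logical; if `TRUE` use a single causal pass instead of
#'   zero-phase forward-backward application.
#' @return A [recording()] object of the same length with filtered axes.
#' @export
bandpass_filter <- function(rec, low_hz = 0.1, high_hz = 12, order = 3L,
                            causal = FALSE) {
  stopifnot(inherits(rec, "sigspot_recording"))
  nyq <- rec$sample_rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf(
      "configuration error: cutoffs must satisfy 0 < low (%g) < high (%g) < Nyquist (%g)",
      low_hz, high_hz, nyq))
  if (order < 1L) stop("configuration error: filter order must be >= 1")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec$data
  for (j in 1:3) {
    out[, j] <- if (causal) {
      as.numeric(signal::filter(bf, rec$data[, j]))
    } else {
      filtfilt_zi(bf$b, bf$a, rec$data[, j])
    }
  }
  filtered <- recording(out, sample_rate_hz = rec$sample_rate_hz,
                        session_id = rec$session_id, task_label = rec$task_label,
                        sensor_range_g = Inf)
  filtered
}

# Steady-state initial filter state for a unit-step input (direct form II
# transposed): the state that makes the filter start in equilibrium, so a
# constant input produces its steady-state output from sample one.
lfilter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  if (n == 1L) return(numeric(0))
  # companion matrix of a (transposed state update)
  A <- rbind(-a[-1], cbind(diag(1, n - 2L, n - 2L), numeric(n - 2L)))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - t(A), B)
}

# One causal pass in direct form II transposed with initial state zi.
df2t_filter <- function(b, a, x, zi) {
  b <- b / a[1]; a <- a / a[1]
  nst <- max(length(a), length(b)) - 1L
  a <- c(a, numeric(nst + 1L - length(a)))
  b <- c(b, numeric(nst + 1L - length(b)))
  z <- c(zi, numeric(nst - length(zi)))
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1L] * x[i] + z[1L]
    if (nst > 1L)
      z[seq_len(nst - 1L)] <- b[2:nst] * x[i] + z[2:nst] - a[2:nst] * y[i]
    z[nst] <- b[nst + 1L] * x[i] - a[nst + 1L] * y[i]
    }
  y
}

# Zero-phase filtering: odd-reflection padding at both ends plus
# steady-state initial conditions, applied forward then backward. Keeps
# constant signals transient-free, which matters for a 0.1 Hz high-pass
# corner on short recordings.
filtfilt_zi <- function(b, a, x) {
  n <- length(x)
  pad <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  ext <- c(2 * x[1] - x[(pad + 1L):2L],
           x,
           2 * x[n] - x[(n - 1L):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- df2t_filter(b, a, ext, zi * ext[1L])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}
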