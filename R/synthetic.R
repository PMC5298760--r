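#' Configuration for the synthetic cleaning-session generator
#'
#' The generator emulates multi-day wrist-worn recordings of periodic
#' cleaning gestures: bouts of repeated strokes concentrated on one
#' acceleration axis per bout, separated by idle gaps, with per-repetition
#' period and amplitude jitter, high-frequency muscle-vibration noise,
#' occasional spikes, and low-amplitude coloured noise on the non-dominant
#' axes. Defaults describe a plausible wiping/sweeping stroke at 40 Hz:
#' 1.2 s mean period (single motions stay under two seconds), 1 g stroke
#' amplitude with 20% repetition-to-repetition variability, 0.05 g vibration
#' noise, 0.5 g spikes at 0.2 per second, and 4 s idle gaps between bouts.
#'
#' @param sample_rate_hz sampling rate (default 40).
#' @param n_sessions number of recording days (default 5).
#' @param session_duration_s session length in seconds (default 40; must
#'   accommodate the scheduled bouts and gaps).
#' @param repetitions_per_bout strokes per bout (default 5).
#' @param period_mean_s mean stroke period in seconds (default 1.2; must not
#'   exceed 2).
#' @param period_jitter,amplitude_jitter relative uniform jitter in `[0, 1)`
#'   applied per repetition (defaults 0.15 and 0.2).
#' @param amplitude_mean_g mean stroke amplitude in g (default 1).
#' @param dominant_axis_schedule character vector giving each bout's dominant
#'   axis (default `c("X", "Y")`, i.e., two bouts per session).
#' @param spike_rate_hz expected spikes per second (default 0.2).
#' @param spike_magnitude_g spike amplitude scale in g (default 0.5).
#' @param vibration_noise_std_g standard deviation of the muscle-vibration
#'   noise, in g (default 0.12). This component is band-limited to the
#'   physiological tremor band (8--12 Hz) and present only while the arm is
#'   moving, so it superimposes local peaks on the strokes themselves --
#'   the signal character that makes small extension boundaries stop short
#'   of the true stroke extrema.
#' @param sensor_noise_std_g white accelerometer noise floor on all axes at
#'   all times, in g (default 0.02).
#' @param sway_std_g slow coloured (AR(1)) incidental wrist-motion noise on
#'   all axes, in g (default 0.04).
#' @param idle_gap_s idle gap before each bout and at the session end, in
#'   seconds (default 4, one full analysis window).
#' @param seed base RNG seed (default 1).
#' @return A validated list of class `sigspot_generator_config`.
#' @export
generator_config <- function(sample_rate_hz = 40, n_sessions = 5L,
                             session_duration_s = 40,
                             repetitions_per_bout = 5L,
                             period_mean_s = 1.2, period_jitter = 0.15,
                             amplitude_mean_g = 1, amplitude_jitter = 0.2,
                             dominant_axis_schedule = c("X", "Y"),
                             spike_rate_hz = 0.2, spike_magnitude_g = 0.5,
                             vibration_noise_std_g = 0.12,
                             sensor_noise_std_g = 0.02,
                             sway_std_g = 0.04,
                             idle_gap_s = 4, seed = 1L) {
  cfg <- list(sample_rate_hz = sample_rate_hz, n_sessions = as.integer(n_sessions),
              session_duration_s = session_duration_s,
              repetitions_per_bout = as.integer(repetitions_per_bout),
              period_mean_s = period_mean_s, period_jitter = period_jitter,
              amplitude_mean_g = amplitude_mean_g,
              amplitude_jitter = amplitude_jitter,
              dominant_axis_schedule = match.arg(dominant_axis_schedule,
                                                 c("X", "Y", "Z"),
                                                 several.ok = TRUE),
              spike_rate_hz = spike_rate_hz,
              spike_magnitude_g = spike_magnitude_g,
              vibration_noise_std_g = vibration_noise_std_g,
              sensor_noise_std_g = sensor_noise_std_g,
              sway_std_g = sway_std_g,
              idle_gap_s = idle_gap_s, seed = as.integer(seed))
  with(cfg, {
    stopifnot(sample_rate_hz > 0, session_duration_s > 0,
              repetitions_per_bout >= 1, amplitude_mean_g > 0,
              spike_rate_hz >= 0, spike_magnitude_g >= 0,
              vibration_noise_std_g >= 0, sensor_noise_std_g >= 0,
              sway_std_g >= 0, idle_gap_s >= 0)
    if (!(period_mean_s > 0 && period_mean_s <= 2))
      stop("period_mean_s must be in (0, 2]: a single motion must fit the analysis window")
    if (!(period_jitter >= 0 && period_jitter < 1) ||
        !(amplitude_jitter >= 0 && amplitude_jitter < 1))
      stop("jitters must lie in [0, 1)")
  })
  structure(cfg, class = "sigspot_generator_config")
}

# One stroke: dip from 0 to -A (raised cosine), fast rise from -A to +A (the
# significant series), slow fall from +A back to 0. Segment junctions have
# zero slope, so the concatenated signal is piecewise smooth. Returns the
# samples plus the within-stroke indices (1-based) of trough and peak.
stroke_wave <- function(n_samples, amplitude,
                        frac = c(dip = 0.2, rise = 0.3, fall = 0.5)) {
  n1 <- max(2L, round(frac[["dip"]] * n_samples))
  n2 <- max(2L, round(frac[["rise"]] * n_samples))
  n3 <- max(2L, n_samples - n1 - n2)
  dip <- -amplitude / 2 * (1 - cos(pi * seq_len(n1) / n1))
  rise <- -amplitude * cos(pi * seq_len(n2) / n2)
  fall <- amplitude / 2 * (1 + cos(pi * seq_len(n3) / n3))
  list(samples = c(dip, rise, fall), trough = n1, peak = n1 + n2)
}

#' Generate one annotated synthetic session
#'
#' Bouts follow `dominant_axis_schedule`, each preceded by an idle gap;
#' per-repetition period and amplitude are jittered uniformly. Ground-truth
#' significant intervals are the rising transition of each stroke, from the
#' stroke trough (-A) to its peak (+A), in half-open 0-based coordinates.
#' Fully deterministic given `(config$seed, session_index)`.
#'
#' @param config a [generator_config()].
#' @param session_index integer session number (drives the sub-seed).
#' @param amplitude_scale,period_scale optional per-session drift multipliers
#'   (used by [generate_dataset()]).
#' @return A list of class `sigspot_session` with `recording`, `truth`
#'   (an [annotations()] object) and `metadata` (realised periods/amplitudes
#'   per repetition).
#' @export
generate_session <- function(config, session_index = 1L,
                             amplitude_scale = 1, period_scale = 1) {
  stopifnot(inherits(config, "sigspot_generator_config"))
  fs <- config$sample_rate_hz
  n_total <- round(config$session_duration_s * fs)
  sub_seed <- (config$seed + 10007L * as.integer(session_index)) %% .Machine$integer.max
  with_seed(sub_seed, {
    data <- matrix(0, nrow = n_total, ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
    gap <- round(config$idle_gap_s * fs)
    pos <- gap  # 0-based sample cursor
    starts <- ends <- integer(0)
    periods <- amps <- numeric(0)
    bout_from <- bout_to <- integer(0)
    ax_idx <- c(X = 1L, Y = 2L, Z = 3L)
    for (b in seq_along(config$dominant_axis_schedule)) {
      ax <- ax_idx[[config$dominant_axis_schedule[[b]]]]
      bout_from <- c(bout_from, pos)
      for (r in seq_len(config$repetitions_per_bout)) {
        T_r <- config$period_mean_s * period_scale *
          (1 + config$period_jitter * stats::runif(1, -1, 1))
        A_r <- config$amplitude_mean_g * amplitude_scale *
          (1 + config$amplitude_jitter * stats::runif(1, -1, 1))
        n_r <- max(6L, round(T_r * fs))
        if (pos + n_r > n_total)
          stop("config error: scheduled bouts do not fit the session duration")
        w <- stroke_wave(n_r, A_r)
        data[(pos + 1L):(pos + n_r), ax] <-
          data[(pos + 1L):(pos + n_r), ax] + w$samples
        starts <- c(starts, pos + w$trough - 1L)   # trough sample, 0-based
        ends <- c(ends, pos + w$peak)              # half-open past the peak
        periods <- c(periods, n_r / fs)
        amps <- c(amps, A_r)
        pos <- pos + n_r
      }
      bout_to <- c(bout_to, pos)
      pos <- pos + gap
    }
    if (pos - gap > n_total)
      stop("config error: scheduled bouts do not fit the session duration")
    # muscle vibration: 8-12 Hz band-limited noise, present only while the
    # arm moves, superimposing local peaks on the strokes themselves
    if (config$vibration_noise_std_g > 0 && length(bout_from) > 0L) {
      bp <- signal::butter(2, c(8, 12) / (fs / 2), type = "pass")
      for (b in seq_along(bout_from)) {
        span <- (bout_from[b] + 1L):bout_to[b]
        for (j in 1:3) {
          tremor <- as.numeric(signal::filter(bp, stats::rnorm(length(span))))
          s <- stats::sd(tremor)
          if (s > 0)
            data[span, j] <- data[span, j] +
              tremor * (config$vibration_noise_std_g / s)
        }
      }
    }
    # slow incidental wrist motion (coloured noise) and sensor noise floor
    for (j in 1:3) {
      if (config$sway_std_g > 0) {
        ar <- as.numeric(stats::filter(stats::rnorm(n_total), 0.95,
                                       method = "recursive"))
        s <- stats::sd(ar)
        if (s > 0) data[, j] <- data[, j] + ar * (config$sway_std_g / s)
      }
      if (config$sensor_noise_std_g > 0)
        data[, j] <- data[, j] + stats::rnorm(n_total, 0, config$sensor_noise_std_g)
    }
    if (config$spike_rate_hz > 0 && config$spike_magnitude_g > 0) {
      n_spikes <- stats::rpois(1, config$spike_rate_hz * config$session_duration_s)
      if (n_spikes > 0) {
        at <- sample.int(n_total, n_spikes, replace = TRUE)
        axs <- sample.int(3L, n_spikes, replace = TRUE)
        mag <- config$spike_magnitude_g * stats::runif(n_spikes, 0.5, 1) *
          sample(c(-1, 1), n_spikes, replace = TRUE)
        for (i in seq_len(n_spikes)) data[at[i], axs[i]] <- data[at[i], axs[i]] + mag[i]
      }
    }
    data <- pmin(pmax(data, -6), 6)  # sensor clipping at +/- 6 g
    sid <- sprintf("synthetic-day%02d", session_index)
    rec <- recording(data, sample_rate_hz = fs, session_id = sid,
                     task_label = "synthetic-cleaning")
    truth <- annotations(sid, starts, ends, TRUE, n_samples = n_total)
    structure(list(recording = rec, truth = truth,
                   metadata = list(periods_s = periods, amplitudes_g = amps,
                                   sub_seed = sub_seed)),
              class = "sigspot_session")
  })
}

#' @export
print.sigspot_session <- function(x, ...) {
  cat(sprintf("<sigspot_session> '%s': %d samples, %d significant intervals\n",
              x$recording$session_id, x$recording$n_samples, nrow(x$truth)))
  invisible(x)
}

#' Generate a multi-day annotated synthetic dataset
#'
#' Sessions receive distinct sub-seeds and mild per-session drift of the
#' amplitude and period means (5% s.d. log-normal-like multipliers), modelling
#' day-to-day variation of the same subject; suitable for
#' leave-one-session-out cross-validation.
#'
#' @param config a [generator_config()].
#' @param n_sessions number of sessions (default `config$n_sessions`;
#'   must be >= 2).
#' @return A list of `sigspot_session` objects.
#' @export
generate_dataset <- function(config, n_sessions = config$n_sessions) {
  stopifnot(inherits(config, "sigspot_generator_config"))
  if (n_sessions < 2L) stop("a dataset needs at least 2 sessions")
  drifts <- with_seed(config$seed, list(
    amp = exp(stats::rnorm(n_sessions, 0, 0.05)),
    per = exp(stats::rnorm(n_sessions, 0, 0.05))))
  lapply(seq_len(n_sessions), function(i)
    generate_session(config, i, amplitude_scale = drifts$amp[i],
                     period_scale = drifts$per[i]))
}
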