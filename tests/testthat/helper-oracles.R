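# Independent brute-force oracles used across tests. These re-derive the
# boundary-extension and matching semantics with the plainest possible code,
# so the package implementation is checked against a second route.

# Iterative brute-force end extension: repeatedly take the argmax of the
# clipped right window (ties -> closest index), stop at a fixed point.
# 0-based indices, like the package API.
oracle_extend_end <- function(series, initial_end, alpha_upper) {
  n <- length(series)
  cur <- initial_end
  repeat {
    win_idx <- cur:min(cur + alpha_upper, n - 1)
    vals <- series[win_idx + 1]
    best <- win_idx[which(vals == max(vals))]
    nxt <- best[which.min(abs(best - cur))]
    if (nxt == cur) return(cur)
    cur <- nxt
  }
}

oracle_extend_start <- function(series, initial_start, alpha_lower) {
  cur <- initial_start
  repeat {
    win_idx <- max(cur - alpha_lower, 0):cur
    vals <- series[win_idx + 1]
    best <- win_idx[which(vals == min(vals))]
    nxt <- best[which.min(abs(best - cur))]
    if (nxt == cur) return(cur)
    cur <- nxt
  }
}

# Exhaustive optimal one-to-one interval matching (maximises matched pairs)
# for small instances; used to bound the greedy matcher.
oracle_match_count <- function(spotted, truth, min_overlap = 0.5) {
  ns <- nrow(spotted); nt <- nrow(truth)
  if (ns == 0 || nt == 0) return(0L)
  J <- outer(seq_len(ns), seq_len(nt), function(i, j) {
    inter <- pmax(0, pmin(spotted$global_end[i], truth$global_end[j]) -
                    pmax(spotted$global_start[i], truth$global_start[j]))
    un <- (spotted$global_end[i] - spotted$global_start[i]) +
      (truth$global_end[j] - truth$global_start[j]) - inter
    ifelse(un > 0, inter / un, 0)
  })
  ok <- J >= min_overlap
  best <- 0L
  recurse <- function(i, used, count) {
    if (i > ns) { best <<- max(best, count); return(invisible()) }
    recurse(i + 1L, used, count)  # leave spotted i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && ok[i, j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nt), 0L)
  best
}

# A frame object built directly from a 3-column matrix, bypassing make_frames.
frame_from_matrix <- function(m, global_start = 0L, sample_rate = 40) {
  structure(list(frame_index = 1L, global_start = as.integer(global_start),
                 window_len = nrow(m), sample_rate_hz = sample_rate,
                 data = {
                   m <- as.matrix(m); colnames(m) <- c("x", "y", "z"); m
                 }),
            class = "sigspot_frame")
}

clean_config <- function(seed = 42, ...) {
  generator_config(vibration_noise_std_g = 0, spike_rate_hz = 0,
                   sensor_noise_std_g = 0, sway_std_g = 0, seed = seed, ...)
}
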