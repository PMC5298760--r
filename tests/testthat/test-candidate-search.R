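test_that("dominant axis maximises the tail-average spread with X>Y>Z ties", {
  m <- cbind(0:9, c(0, 0, 0, 0, 0, 5, 5, 5, 5, 5), rep(2, 10))
  res <- identify_dominant_axis(frame_from_matrix(m), tail_fraction = 0.1)
  expect_equal(res$spread_per_axis, c(X = 9, Y = 5, Z = 0))
  expect_equal(res$axis, "X")

  same <- cbind(1:8, 1:8, 1:8)
  res2 <- identify_dominant_axis(frame_from_matrix(same))
  expect_true(all(res2$spread_per_axis == res2$spread_per_axis[1]))
  expect_equal(res2$axis, "X")

  const <- matrix(3, nrow = 6, ncol = 3)
  res3 <- identify_dominant_axis(frame_from_matrix(const))
  expect_equal(unname(res3$spread_per_axis), c(0, 0, 0))
  expect_equal(res3$axis, "X")
})

test_that("threshold is the series mean", {
  expect_equal(compute_threshold(c(0, 2, 0, 2, 0)), 0.8)
  expect_equal(compute_threshold(rep(3.3, 5)), 3.3)
  expect_equal(compute_threshold(c(-1, 1)), 0)
  expect_error(compute_threshold(numeric(0)), "non-empty")
})

test_that("event detection finds strict ascending crossings only", {
  ev <- detect_events(c(0, 2, 0, 2, 0), 0.8)
  expect_equal(ev$i_low, c(0L, 2L))
  expect_equal(ev$i_high, ev$i_low + 1L)

  expect_equal(nrow(detect_events(rep(1, 5), 1)), 0L)       # at-threshold, strict
  expect_equal(nrow(detect_events(5:1, 3)), 0L)             # descending only
  # brute-force scan over random series agrees
  set.seed(3)
  for (rep in 1:20) {
    s <- runif(50, -1, 1); thr <- runif(1, -0.5, 0.5)
    ev <- detect_events(s, thr)
    brute <- which(s[-50] < thr & s[-1] > thr) - 1L
    expect_equal(ev$i_low, brute)
  }
})

test_that("end extension follows the worked trace and clips at boundaries", {
  s <- c(0, 1, 0.5, 2, 1, 3, 0)
  expect_equal(extend_end(s, 1, 2), 5L)
  expect_equal(extend_end(s, 5, 2), 5L)          # already the window max
  expect_equal(extend_end(s, length(s) - 1, 3), 6L)  # clipped to itself
})

test_that("start extension mirrors end extension", {
  s <- c(0, 3, 1, 2, 0.5, 1, 2)
  expect_equal(extend_start(s, 5, 2), 4L)
  expect_equal(extend_start(s, 0, 4), 0L)
  expect_equal(extend_start(c(5, 1, 2, 3), 1, 3), 1L)  # already minimal
})

test_that("extensions are idempotent and return fixed points on random input", {
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(5:120, 1)
    s <- runif(n, -1, 1)
    if (rep %% 4 == 0) s <- round(s, 1)  # induce plateaus/ties
    a <- sample(1:15, 1)
    i0 <- sample(0:(n - 1), 1)
    e <- extend_end(s, i0, a)
    expect_identical(extend_end(s, e, a), e)
    # fixed point: e attains the max of its own right window
    win <- s[(e + 1):min(e + a + 1, n)]
    expect_equal(s[e + 1], max(win))
    st <- extend_start(s, i0, a)
    expect_identical(extend_start(s, st, a), st)
    win2 <- s[max(st - a + 1, 1):(st + 1)]
    expect_equal(s[st + 1], min(win2))
  }
})

test_that("one full sine period yields one candidate from waveform minimum to maximum", {
  # one period of -cos sampled off-grid so no sample sits exactly on the
  # mean: starts at the minimum, peaks mid-frame, single ascending crossing
  x <- -cos(2 * pi * ((0:159) + 0.5) / 160)
  cand <- search_candidates(frame_from_matrix(cbind(x, 0, 0)),
                            boundary_params(9, 12))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$axis, "X")
  # closed form: sampled minimum reachable leftward is index 0; the sampled
  # maximum is the 79/80 tie, resolved to 79 (closest to the search point)
  expect_equal(cand$start, 0L)
  expect_equal(cand$end, 79L)
  expect_true(cand$start <= cand$i_low && cand$i_high <= cand$end)
})

test_that("search_candidates handles sine bursts, constants and degenerate frames", {
  # constant frame: no events, no candidates
  expect_equal(nrow(search_candidates(frame_from_matrix(matrix(1, 160, 3)),
                                      boundary_params())), 0L)
  # two separated sine bursts -> two disjoint candidates
  burst <- sin(2 * pi * seq(0, 1, length.out = 41))[1:40]
  x <- c(rep(0, 20), burst, rep(0, 40), burst, rep(0, 20))
  cand <- search_candidates(frame_from_matrix(cbind(x, 0, 0)),
                            boundary_params(5, 5))
  expect_equal(nrow(cand), 2L)
  expect_lte(cand$end[1], cand$start[2])
  # ordering invariant: start <= i_low < i_high <= end
  expect_true(all(cand$start <= cand$i_low & cand$i_low < cand$i_high &
                    cand$i_high <= cand$end))
})

test_that("merging drops duplicates above half-overlap, keeping the longest", {
  base <- data.frame(frame_index = c(3L, 4L), axis = "X",
                     start = 0L, end = 59L, i_low = 10L, i_high = 11L,
                     global_start = c(100L, 100L), global_end = c(160L, 160L),
                     stringsAsFactors = FALSE)
  m <- merge_candidates(list(base[1, ], base[2, ]))
  expect_equal(nrow(m), 1L)
  expect_equal(m$frame_index, 3L)  # tie on length -> earliest frame

  # overlap exactly 50% of the shorter: both kept
  two <- base; two$global_start <- c(100L, 130L); two$global_end <- c(160L, 190L)
  expect_equal(nrow(merge_candidates(two)), 2L)

  # a clipped fragment inside a longer candidate is absorbed by the longer one
  frag <- base
  frag$frame_index <- c(3L, 4L)
  frag$global_start <- c(120L, 100L); frag$global_end <- c(160L, 170L)
  kept <- merge_candidates(frag)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$global_end - kept$global_start, 70L)

  expect_equal(nrow(merge_candidates(list())), 0L)
})
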