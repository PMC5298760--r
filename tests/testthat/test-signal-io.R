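test_that("recording CSV parsing handles headers, timestamps and bad rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.000,0.1,0.2,0.3", "0.025,0.2,0.3,0.4", "0.050,0.3,0.4,0.5"), p)
  rec <- read_recording(p, sample_rate = 40)
  expect_equal(rec$n_samples, 3L)
  expect_equal(rec$data[, "x"], c(0.1, 0.2, 0.3))

  # header + 3-column variant
  writeLines(c("x_g,y_g,z_g", "0.1,0.2,0.3", "0.4,0.5,0.6"), p)
  expect_equal(read_recording(p)$data[2, "z"], 0.6, ignore_attr = TRUE)

  writeLines(character(0), p)
  expect_error(read_recording(p), "empty")

  writeLines(c("0.0,0.1,0.2,0.3", "0.025,oops,0.3,0.4"), p)
  expect_error(read_recording(p), "line 2")

  writeLines(c("0.050,0.1,0.2,0.3", "0.025,0.2,0.3,0.4"), p)
  expect_error(read_recording(p), "monotone|increasing")
})

test_that("write_recording round-trips a recording exactly", {
  set.seed(7)
  rec <- recording(matrix(runif(30, -2, 2), ncol = 3), sample_rate_hz = 40,
                   session_id = "rt")
  p <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, p)
  back <- read_recording(p, sample_rate = 40, session_id = "rt")
  expect_identical(back$data, rec$data)
  expect_identical(back$n_samples, rec$n_samples)
})

test_that("recording validation enforces finiteness and sensor range", {
  expect_error(recording(matrix(c(1, NA, 0), ncol = 3)), "finite")
  expect_error(recording(matrix(c(7, 0, 0), ncol = 3)), "range")
  expect_silent(recording(matrix(c(7, 0, 0), ncol = 3), sensor_range_g = Inf))
})

test_that("annotations are validated, sorted, and round-trip through CSV", {
  ann <- annotations("s1", c(50, 10), c(60, 20), TRUE, n_samples = 100)
  expect_equal(ann$start_sample, c(10L, 50L))
  expect_error(annotations("s1", 10, 10), "start_sample < end_sample")
  expect_error(annotations("s1", c(0, 5), c(10, 15), TRUE), "overlap")
  expect_error(annotations("s1", 0, 200, TRUE, n_samples = 100), "past the end")
  p <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, p)
  expect_equal(as.data.frame(read_annotations(p)), as.data.frame(ann))
})

test_that("band-pass filter passes the band, rejects DC, attenuates stopband", {
  fs <- 40; n <- 1000; t <- (0:(n - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  mk <- function(v) recording(cbind(v, 0, 0), fs, sensor_range_g = Inf)
  sine5 <- sin(2 * pi * 5 * t)
  out5 <- bandpass_filter(mk(sine5))$data[, 1]
  expect_lt(abs(rms(out5) - rms(sine5)) / rms(sine5), 0.05)

  dc <- rep(1.5, n)
  expect_lt(rms(bandpass_filter(mk(dc))$data[, 1]), 0.05 * 1.5)

  sine18 <- sin(2 * pi * 18 * t)
  expect_lt(rms(bandpass_filter(mk(sine18))$data[, 1]), 0.5 * rms(sine18))

  expect_error(bandpass_filter(mk(sine5), low_hz = 0), "configuration")
  expect_error(bandpass_filter(mk(sine5), high_hz = 25), "configuration")
})

test_that("filtering is linear and length-preserving", {
  set.seed(11)
  v <- rnorm(400)
  rec1 <- recording(cbind(v, 0, 0), 40, sensor_range_g = Inf)
  rec3 <- recording(cbind(3 * v, 0, 0), 40, sensor_range_g = Inf)
  f1 <- bandpass_filter(rec1)$data[, 1]
  f3 <- bandpass_filter(rec3)$data[, 1]
  expect_equal(length(f1), 400L)
  expect_lt(max(abs(f3 - 3 * f1)) / max(abs(f1)), 1e-9)
})

test_that("causal filter mode differs from zero-phase but keeps length", {
  set.seed(12)
  rec <- recording(cbind(rnorm(200), 0, 0), 40, sensor_range_g = Inf)
  zp <- bandpass_filter(rec)$data[, 1]
  ca <- bandpass_filter(rec, causal = TRUE)$data[, 1]
  expect_equal(length(ca), 200L)
  expect_gt(max(abs(zp - ca)), 0)
})

test_that("frame partition matches the closed-form count and example offsets", {
  rec <- recording(matrix(0, nrow = 400, ncol = 3), 40)
  fr <- make_frames(rec, 4, 0.5)
  expect_length(fr, 4L)
  expect_equal(vapply(fr, `[[`, integer(1), "global_start"), c(0L, 80L, 160L, 240L))
  expect_equal(fr[[1]]$window_len, 160L)

  expect_length(make_frames(recording(matrix(0, 159, 3), 40), 4, 0.5), 0L)
  fr2 <- make_frames(recording(matrix(0, 320, 3), 40), 4, 0)
  expect_length(fr2, 2L)
  expect_equal(fr2[[2]]$global_start, 160L)
})

test_that("frame count formula agrees with brute-force window enumeration", {
  for (n_r in c(10, 37, 160, 161, 400)) {
    for (w_s in c(0.25, 1, 4)) {
      for (ov in c(0, 0.25, 0.5, 0.75)) {
        rec <- recording(matrix(0, nrow = n_r, ncol = 3), 40)
        w <- round(w_s * 40); stride <- floor(w * (1 - ov))
        if (w < 2 || stride < 1) next
        fr <- make_frames(rec, w_s, ov)
        # brute force: all start offsets on the stride lattice that fit
        starts <- seq(0, max(n_r, 1), by = stride)
        expected <- sum(starts + w <= n_r)
        expect_length(fr, expected)
        if (length(fr) > 0) {
          last <- fr[[length(fr)]]
          expect_lte(last$global_start + last$window_len, n_r)
        }
      }
    }
  }
})
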