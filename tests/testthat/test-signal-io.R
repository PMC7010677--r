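test_that("recording round-trips through CSV and validates its inputs", {
  set.seed(1)
  rec <- recording(list(x = rnorm(30), y = rnorm(30), z = rnorm(30)),
                   rate_hz = 100, subject_id = "S1", task = "Rest-1",
                   pathology = "PD")
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  back <- read_recording(f, rate_hz = 100, task = "Rest-1",
                         pathology = "PD")
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_identical(back$axes, c("x", "y", "z"))

  # rate inferred from the time column
  back2 <- read_recording(f)
  expect_equal(back2$rate_hz, 100, tolerance = 1e-9)

  # a tiny literal file parses to the declared shape
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ax,ay,az", "1,2,3", "4,5,6", "7,8,9"), f2)
  r3 <- read_recording(f2, rate_hz = 10)
  expect_equal(length(r3), 3L)
  expect_equal(length(r3$axes), 3L)
  expect_equal(r3$samples$ay, c(2, 5, 8))

  expect_error(read_recording(tempfile(), rate_hz = 1), "not found")
  # non-numeric token reported with its row and column
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a", "1", "2", "3", "4", "oops", "6"), f3)
  expect_error(read_recording(f3, rate_hz = 1), "row 5.*column 'a'")
  # ragged rows reported with row context
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3", "5,6"), f4)
  expect_error(read_recording(f4, rate_hz = 1), "row 3")

  expect_error(recording(list(a = 1:3, b = 1:2), 100), "same length")
  expect_error(recording(1:5, 0), "positive")
})

test_that("downsampling preserves the tremor-band spectrum", {
  n <- 15000
  t <- (seq_len(n) - 1) / 1500
  # clinical-style decimation: 1500 Hz -> 100 Hz, 15000 -> 1000 samples
  rec <- recording(sin(2 * pi * 2 * t), rate_hz = 1500)
  dn <- downsample(rec, 100)
  expect_equal(dn$rate_hz, 100)
  expect_equal(length(dn), 1000L)

  # DC invariance
  const <- downsample(recording(rep(1.7, 3000), 1500), 100)
  expect_equal(unique(round(const$samples[[1]], 9)), 1.7)

  # amplitude of in-band tones preserved within 2%; the oracle is a
  # least-squares fit of the known-frequency quadrature pair, not a
  # package routine
  tone_amp <- function(x, f, rate) {
    tt <- (seq_along(x) - 1) / rate
    b <- coef(lm(x ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt) - 1))
    sqrt(sum(b^2))
  }
  for (f in c(1, 5, 14)) {
    rec <- recording(0.8 * sin(2 * pi * f * t + 0.3), rate_hz = 1500)
    y <- downsample(rec, 100)$samples[[1]]
    expect_lt(abs(tone_amp(y, f, 100) - 0.8) / 0.8, 0.02)
  }
  # FFT peak stays at the tone frequency
  y <- downsample(recording(sin(2 * pi * 2 * t), 1500), 100)$samples[[1]]
  spec <- Mod(fft(y))[1:500]
  expect_equal(((which.max(spec) - 1) * 100 / 1000), 2, tolerance = 0.101)

  expect_error(downsample(recording(1:10, 100), 100), "below")
  expect_error(downsample(recording(1:10, 100), 200), "below")
})

test_that("affine min-max scaling is exact and invertible", {
  s <- scale_affine(c(0, 1, 3), 0, 1)
  expect_equal(s$series, c(0, 1 / 3, 1))

  set.seed(2)
  x <- rnorm(200, sd = 3)
  sc <- scale_affine(x, 0, 0.5)
  expect_equal(min(sc$series), 0)
  expect_equal(max(sc$series), 0.5)
  expect_lt(max(abs(invert_affine(sc$transform, sc$series) - x)), 1e-12)
  expect_equal(apply_affine(sc$transform, x), sc$series)

  expect_error(scale_affine(rep(2, 5)), "constant")
  expect_error(scale_affine(1:3, 1, 1), "exceed")
})

test_that("segmentation tiles the series prefix exactly", {
  expect_length(segment_series(seq_len(1000), 400, 400), 2L)
  expect_length(segment_series(seq_len(400), 400), 1L)
  expect_length(segment_series(seq_len(399), 400), 0L)

  x <- rnorm(1037)
  w <- segment_series(x, 100, 100)
  expect_true(all(lengths(w) == 100))
  expect_identical(unlist(w), x[seq_len(1000)])  # gapless tiling
  # overlapping windows start at 1, 1 + stride, ...
  w2 <- segment_series(x, 100, 25)
  expect_identical(w2[[2]], x[26:125])
  expect_error(segment_series(x, 1), "at least 2")
})
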