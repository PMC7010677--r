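test_that("voluntary parameter draws match their uniform laws", {
  set.seed(101)
  p <- sample_voluntary_params(10000)
  expect_true(all(p$a >= 0 & p$a <= 0.25))
  expect_true(all(p$f >= 0 & p$f <= 3))
  expect_true(all(p$phi >= 0 & p$phi <= pi))
  expect_lt(abs(mean(p$a) - 0.125), 0.005)

  # Kolmogorov-Smirnov distance below the 1% critical value on each
  # rescaled parameter (D_crit ~ 1.628 / sqrt(n))
  crit <- 1.628 / sqrt(10000)
  for (u in list(p$a / 0.25, p$f / 3, p$phi / pi)) {
    d <- suppressWarnings(ks.test(u, "punif")$statistic)
    expect_lt(d, crit)
  }

  set.seed(7); a <- sample_voluntary_params(1)
  set.seed(7); b <- sample_voluntary_params(1)
  expect_identical(a, b)
})

test_that("voluntary waveform equals its closed form", {
  expect_equal(generate_voluntary(list(a = 0, f = 2, phi = 1), 50, 100),
               rep(0, 50))
  # t = 0.25 s of a 1 Hz sine with a = 0.2: 0.2 * sin(pi / 2)
  v <- generate_voluntary(list(a = 0.2, f = 1, phi = 0), 100, 100)
  expect_equal(v[26], 0.2)
  expect_lt(max(abs(v)), 0.2 + 1e-12)

  set.seed(5)
  for (i in 1:20) {
    p <- sample_voluntary_params(1)
    got <- generate_voluntary(p, 200, 100)
    expect_lt(max(abs(got - oracle_sine(p$a, p$f, p$phi, 200, 100))), 1e-12)
  }
})

test_that("simulated static tremor is band-limited, scaled and reproducible", {
  x <- simulate_static_tremor(2000, 100, seed = 3)
  expect_equal(min(x), 0)
  expect_equal(max(x), 0.5)
  spec <- Mod(fft(x - mean(x)))[2:1000]
  fpk <- (which.max(spec)) * 100 / 2000
  expect_gte(fpk, 4); expect_lte(fpk, 8)

  y1 <- simulate_static_tremor(500, 100, seed = 11)
  y2 <- simulate_static_tremor(500, 100, seed = 11)
  expect_identical(y1, y2)

  # nonstationary envelope when the amplitude walk is on
  env <- abs(x - mean(x))
  thirds <- split(env, cut(seq_along(env), 3))
  expect_gt(sd(vapply(thirds, mean, 1)), 0)

  expect_error(tremor_sim_params(band_hz = c(1, 8)), "3 <= low")
  expect_error(tremor_sim_params(band_hz = c(4, 15)), "3 <= low")
  expect_error(tremor_sim_params(center_hz = 10), "inside")
  expect_error(simulate_static_tremor(100, 100), "2 seconds")
})

test_that("mean tremor periodogram across seeds peaks at the dominant frequency", {
  nseeds <- 100
  n <- 1000
  acc <- numeric(n %/% 2)
  for (s in seq_len(nseeds)) {
    x <- simulate_static_tremor(n, 100, seed = 1000 + s)
    acc <- acc + Mod(fft(x - mean(x)))[2:(n %/% 2 + 1)]^2
  }
  fpk <- which.max(acc) * 100 / n
  expect_lt(abs(fpk - 5), 1)
})

test_that("additive mixing is exact and lands in [0, 1]", {
  set.seed(4)
  v <- runif(100, -0.25, 0.25)
  s <- runif(100, 0, 0.5)
  m <- mix_components(v, s)
  expect_equal(m, v + 0.25 + s)
  expect_lt(max(abs(m - 0.25 - s - v)), 1e-12)  # conservation
  expect_gte(min(m), 0); expect_lte(max(m), 1)

  expect_equal(mix_components(v, rep(0, 100)), v + 0.25)
  expect_equal(mix_components(rep(0, 100), s), s + 0.25)

  expect_error(mix_components(v, s[-1]), "length")
  expect_error(mix_components(v * 3, s), "\\[-0.25, 0.25\\]")
  expect_error(mix_components(v, s * 3), "\\[0, 0.5\\]")
})

test_that("dataset building splits subjects, shifts targets and reproduces", {
  ds <- build_dataset(10, 4, window = 250, seed = 42)
  subj <- lapply(ds, function(s) unique(vapply(s, `[[`, "", "subject_id")))
  expect_length(subj$train, 6L)
  expect_length(subj$validation, 2L)
  expect_length(subj$test, 2L)
  expect_length(intersect(subj$train, subj$validation), 0L)
  expect_length(intersect(subj$train, subj$test), 0L)
  expect_length(intersect(subj$validation, subj$test), 0L)

  for (seg in ds$train[1:4]) {
    expect_equal(seg$shifted_target[seq_len(249)], seg$voluntary_gt[2:250])
    # measurement - offset - tremor recovers the voluntary component
    expect_lt(max(abs(seg$measurement - seg$offset - seg$tremor -
                      (seg$voluntary_gt - seg$offset))), 1e-12)
    expect_gte(min(seg$measurement), 0)
    expect_lte(max(seg$measurement), 1)
  }

  ds2 <- build_dataset(10, 4, window = 250, seed = 42)
  expect_identical(ds, ds2)  # bit-reproducible under a fixed master seed

  expect_error(build_dataset(10, 4, split_fracs = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(build_dataset(3, 4), "n_subjects")
})
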