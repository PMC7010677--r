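test_that("mse matches its definition and scaling laws", {
  x <- c(1, 2, 3.5)
  expect_equal(mse(x, x), 0)
  expect_equal(mse(x + 0.3, x), 0.09)

  set.seed(71)
  a <- runif(400); b <- runif(400)
  acc <- 0
  for (i in 1:400) acc <- acc + (a[i] - b[i])^2  # independent loop oracle
  expect_equal(mse(a, b), acc / 400, tolerance = 1e-12)

  expect_equal(mse(a, b), mse(b, a))                 # symmetry
  expect_equal(mse(3 * a, 3 * b), 9 * mse(a, b))     # quadratic scaling
  expect_equal(mse(a, b, relative = TRUE), mse(a, b) / mean(b^2))
  expect_error(mse(a, b[-1]), "length")
})

test_that("endpoint errors pick the paths' operating points", {
  Tn <- 50
  tgt <- matrix(rnorm(Tn * 4), Tn, 4)
  perfect <- structure(list(forward_estimate = tgt, backward_estimate = tgt),
                       class = "network_output")
  expect_equal(endpoint_errors(perfect, tgt),
               c(forward_last = 0, backward_first = 0))

  # single window, forward off by 0.1 at the last sample only
  one <- structure(list(
    forward_estimate = matrix(c(tgt[-Tn, 1], tgt[Tn, 1] + 0.1)),
    backward_estimate = matrix(tgt[, 1])), class = "network_output")
  e <- endpoint_errors(one, tgt[, 1, drop = FALSE])
  expect_equal(unname(e), c(0.01, 0))

  set.seed(72)
  fwd <- matrix(rnorm(Tn * 6), Tn, 6); bwd <- matrix(rnorm(Tn * 6), Tn, 6)
  out <- structure(list(forward_estimate = fwd, backward_estimate = bwd),
                   class = "network_output")
  tg <- matrix(rnorm(Tn * 6), Tn, 6)
  manual_f <- mean(sapply(1:6, function(j) (fwd[Tn, j] - tg[Tn, j])^2))
  manual_b <- mean(sapply(1:6, function(j) (bwd[1, j] - tg[1, j])^2))
  expect_equal(unname(endpoint_errors(out, tg)), c(manual_f, manual_b))

  # list-of-outputs form
  lst <- lapply(1:6, function(j) structure(
    list(forward_estimate = fwd[, j], backward_estimate = bwd[, j]),
    class = "network_output"))
  expect_equal(endpoint_errors(lst, lapply(1:6, function(j) tg[, j])),
               endpoint_errors(out, tg))
})

test_that("sliding PSD has the documented geometry and peaks", {
  # a 50-sample window at 100 Hz has 2 Hz bins; a 6 Hz tone sits
  # exactly on a bin and every column must peak there
  x6 <- sin(2 * pi * 6 * (0:99) / 100)
  p <- sliding_psd(x6, 100, window = 50, overlap = 45)
  expect_equal(ncol(p), 11L)            # floor((100 - 50) / 5) + 1
  expect_equal(nrow(p), 26L)
  expect_true(all(p >= 0))
  fr <- attr(p, "freq")
  expect_true(all(fr[apply(unclass(p), 2, which.max)] == 6))

  # an off-bin tone (5 Hz) peaks at a neighbouring bin, within the
  # 2 Hz resolution
  x5 <- sin(2 * pi * 5 * (0:99) / 100)
  p5 <- sliding_psd(x5, 100, window = 50, overlap = 45)
  expect_true(all(abs(fr[apply(unclass(p5), 2, which.max)] - 5) <= 2))

  expect_equal(max(abs(sliding_psd(rep(0, 100), 100))), 0)

  # a tone confined to its own bin leaves other bins untouched
  x20 <- 0.7 * sin(2 * pi * 20 * (0:99) / 100)
  p2 <- sliding_psd(x6 + x20, 100, window = 50, overlap = 45)
  keep <- fr != 20
  expect_equal(unclass(p2)[keep, ], unclass(p)[keep, ], tolerance = 1e-9)

  expect_error(sliding_psd(rep(0, 30), 100, window = 50), "shorter")
  expect_error(sliding_psd(x6, 100, window = 50, overlap = 50), "overlap")
})

test_that("the omnibus normality test reproduces reference values", {
  x <- c(0.12, -0.54, 1.31, -0.02, 0.88, -1.10, 0.45, 0.03, -0.77, 1.95,
         -0.33, 0.61, -1.42, 0.27, 0.09, -0.88, 2.10, -0.15, 0.73, -0.29,
         0.51, -1.03, 0.34, 0.92, -0.61)
  # reference statistics computed independently for this fixture
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 1.0487115758233436, tolerance = 1e-9)
  expect_equal(r$p.value, 0.5919365742602827, tolerance = 1e-9)
  r2 <- dagostino_pearson(exp(x))
  expect_equal(r2$statistic, 27.05747593896408, tolerance = 1e-9)
  expect_equal(r2$p.value, 1.3321212393141935e-06, tolerance = 1e-9)
  expect_error(dagostino_pearson(x[1:10]), "at least 20")
})

test_that("spectral population comparison flags shifted bins only", {
  set.seed(73)
  n <- 100; Tn <- 64
  X <- matrix(rnorm(Tn * n), Tn, n)
  s <- spectral_population_compare(X, X, 100)
  expect_true(all(s$table$p_value > 0.99))
  expect_equal(s$table$mean_in, s$table$mean_out)
  expect_equal(s$table$ci_in, s$table$ci_out)
  expect_false(any(s$table$freq == 0))
  # CI half-width is exactly 1.96 sd / sqrt(n)
  expect_equal(s$table$ci_in, 1.96 * s$table$sd_in / sqrt(n))

  # boost one frequency bin's amplitude by ~10 population sd
  f0 <- 10; amp <- 10 * sd(Mod(stats::mvfft(X))[f0 + 1, ]) / (Tn / 2)
  Y <- X + outer(2 * amp * sin(2 * pi * f0 * (0:(Tn - 1)) / Tn),
                 rep(1, n))
  s2 <- spectral_population_compare(X, Y, 100)
  hit <- which.min(abs(s2$table$freq - f0 * 100 / Tn))
  expect_lt(s2$table$p_value[hit], 1e-4)

  expect_error(spectral_population_compare(X[, 1:10], X[, 1:10], 100),
               "at least 20")
  expect_error(spectral_population_compare(X, X[1:10, ], 100), "equal")
})

test_that("method comparison reports ANOVA, pairwise tests and improvement", {
  # hand-checkable improvement: (0.20 - 0.02) / 0.20 * 100 = +90%
  set.seed(74)
  e <- list(net = rep(0.02, 25) + rnorm(25, 0, 1e-9),
            base = rep(0.20, 25) + rnorm(25, 0, 1e-9))
  cm <- compare_methods(e)
  expect_equal(unname(cm$improvement["base"]), 90, tolerance = 0.001)

  # identical groups: no improvement, ANOVA cannot reject
  x <- runif(30)
  cm0 <- compare_methods(list(a = x, b = x))
  expect_equal(unname(cm0$improvement), 0)
  expect_gt(cm0$anova_p, 0.99)

  # 5 pooled-sd separation at n = 100: decisive tests, disjoint CIs
  g1 <- rnorm(100, 0, 1); g2 <- rnorm(100, 5, 1)
  cm2 <- compare_methods(list(lo = g1, hi = g2))
  expect_lt(cm2$pairwise$p_raw[1], 1e-6)
  s <- cm2$summary
  expect_lt(s$mean[1] + s$ci[1], s$mean[2] - s$ci[2])
  expect_lt(cm2$anova_p, 1e-6)

  expect_error(compare_methods(list(a = runif(30))), "two methods")
  expect_error(compare_methods(list(a = runif(30), b = runif(29))),
               "paired")
  expect_error(compare_methods(list(runif(30), runif(30))), "named")
})
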