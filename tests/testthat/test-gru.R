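test_that("a single GRU step follows the gate equations", {
  # all-zero weights: r = z = sigmoid(0) = 0.5, candidate = 0,
  # so h_t = 0.5 * h_prev
  H <- 3
  p0 <- list(Ur = matrix(0, H, 1), Wr = matrix(0, H, H),
             Uz = matrix(0, H, 1), Wz = matrix(0, H, H),
             U = matrix(0, H, 1), W = matrix(0, H, H),
             br = numeric(H), bz = numeric(H), bh = numeric(H))
  h <- c(0.4, -1.2, 2)
  expect_equal(gru_cell_step(0.7, h, p0), 0.5 * h)

  # saturated update gate: h_t -> candidate
  p1 <- p0
  p1$bz <- rep(50, H)
  p1$U <- matrix(1, H, 1)
  expect_equal(gru_cell_step(0.7, h, p1), rep(0.7, H), tolerance = 1e-10)

  # oracle equivalence including saturating regimes
  set.seed(31)
  for (i in 1:25) {
    p <- rand_cell(4, 2, scale = 3)
    x <- rnorm(2, sd = 5); h <- rnorm(4, sd = 5)
    out <- gru_cell_step(x, h, p)
    expect_equal(out, oracle_gru_step(x, h, p), tolerance = 1e-12)
  }
  # gates stay strictly inside (0, 1) away from floating-point
  # saturation (the sigmoid underflows to exact 0/1 beyond |a| ~ 37)
  for (i in 1:25) {
    p <- rand_cell(4, 2, scale = 1)
    x <- rnorm(2); h <- rnorm(4)
    r <- plogis(drop(p$Ur %*% x + p$Wr %*% h) + p$br)
    z <- plogis(drop(p$Uz %*% x + p$Wz %*% h) + p$bz)
    expect_true(all(r > 0 & r < 1 & z > 0 & z < 1))
  }
})

test_that("freezing the update gate at zero freezes the hidden state", {
  set.seed(8)
  path <- rand_path(2, 3)
  for (l in seq_along(path$layers)) {
    path$layers[[l]]$Uz[] <- 0
    path$layers[[l]]$Wz[] <- 0
    path$layers[[l]]$bz[] <- -1e3   # z ~ 0: h_t = h_prev for all t
  }
  out <- network_forward(list(forward = path, backward = path),
                         runif(50))
  expect_equal(diff(range(out$forward_estimate)), 0)
  expect_equal(diff(range(out$backward_estimate)), 0)
})

test_that("compiled stack matches the scalar-loop oracle", {
  set.seed(21)
  for (i in 1:5) {
    path <- rand_path(2, 3)
    x <- runif(10)
    got <- network_forward(list(forward = path, backward = path), x)
    expect_equal(got$forward_estimate,
                 oracle_path_forward(x, path$layers, path$V, path$c),
                 tolerance = 1e-10)
    # backward path: reversed input, output re-reversed
    expect_equal(got$backward_estimate,
                 rev(oracle_path_forward(rev(x), path$layers, path$V,
                                         path$c)),
                 tolerance = 1e-10)
  }
})

test_that("the forward path is causal and ignores the backward weights", {
  set.seed(22)
  pf <- rand_path(2, 4); pb <- rand_path(2, 4)
  x <- runif(60)
  base <- network_forward(list(forward = pf, backward = pb), x)

  # replacing every backward weight leaves the forward estimate
  # bit-identical (the two paths share nothing)
  pb2 <- rand_path(2, 4)
  alt <- network_forward(list(forward = pf, backward = pb2), x)
  expect_identical(alt$forward_estimate, base$forward_estimate)
  expect_false(identical(alt$backward_estimate, base$backward_estimate))

  # perturbing sample t0 leaves forward estimates before t0 untouched
  # (and backward estimates after t0, by time reversal)
  for (t0 in c(10, 35, 60)) {
    xp <- x; xp[t0] <- xp[t0] + 0.5
    pert <- network_forward(list(forward = pf, backward = pb), xp)
    if (t0 > 1)
      expect_identical(pert$forward_estimate[seq_len(t0 - 1)],
                       base$forward_estimate[seq_len(t0 - 1)])
    expect_false(isTRUE(all.equal(pert$forward_estimate[t0],
                                  base$forward_estimate[t0])))
    if (t0 < 60)
      expect_identical(pert$backward_estimate[(t0 + 1):60],
                       base$backward_estimate[(t0 + 1):60])
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(23)
  path <- rand_path(2, 3)
  x <- matrix(runif(16 * 2), 16, 2)
  y <- matrix(runif(16 * 2), 16, 2)
  g <- tremornet:::cpp_path_grad(x, y, path$layers, path$V, path$c, 0L)
  eps <- 1e-6
  loss_at <- function(layers, V, cb)
    tremornet:::cpp_path_grad(x, y, layers, V, cb, 0L)$loss
  # spot-check a handful of coordinates in every weight family
  for (l in 1:2) for (nm in c("Ur", "Wz", "W", "bh")) {
    w <- path$layers[[l]][[nm]]
    for (idx in seq_len(min(3, length(w)))) {
      lp <- path$layers; lp[[l]][[nm]][idx] <- w[idx] + eps
      lm_ <- path$layers; lm_[[l]][[nm]][idx] <- w[idx] - eps
      fd <- (loss_at(lp, path$V, path$c) - loss_at(lm_, path$V, path$c)) /
        (2 * eps)
      expect_equal(g$layers[[l]][[nm]][idx], fd, tolerance = 1e-5)
    }
  }
  fdV <- (loss_at(path$layers, path$V + c(eps, 0, 0), path$c) -
          loss_at(path$layers, path$V - c(eps, 0, 0), path$c)) / (2 * eps)
  expect_equal(g$V[1], fdV, tolerance = 1e-5)
})

test_that("tanh candidate activation is supported end to end", {
  set.seed(24)
  path <- rand_path(1, 2)
  x <- runif(8)
  got <- network_forward(list(forward = path, backward = path), x,
                         activation = "tanh")
  expect_equal(got$forward_estimate,
               oracle_path_forward(x, path$layers, path$V, path$c, "tanh"),
               tolerance = 1e-10)
})
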