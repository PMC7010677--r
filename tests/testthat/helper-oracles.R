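# Independent oracles, written as plain scalar loops so they share no
# code path with the package's vectorized / compiled implementations.

# One GRU step, unit by unit.
oracle_gru_step <- function(x_t, h_prev, p, activation = "relu") {
  H <- length(h_prev)
  sig <- function(a) 1 / (1 + exp(-a))
  r <- z <- hc <- h <- numeric(H)
  for (i in seq_len(H)) {
    ar <- p$br[i]; az <- p$bz[i]; ac <- p$bh[i]
    for (j in seq_along(x_t)) {
      ar <- ar + p$Ur[i, j] * x_t[j]
      az <- az + p$Uz[i, j] * x_t[j]
      ac <- ac + p$U[i, j] * x_t[j]
    }
    for (j in seq_len(H)) {
      ar <- ar + p$Wr[i, j] * h_prev[j]
      az <- az + p$Wz[i, j] * h_prev[j]
    }
    r[i] <- sig(ar); z[i] <- sig(az)
  }
  for (i in seq_len(H)) {
    ac <- p$bh[i]
    for (j in seq_along(x_t)) ac <- ac + p$U[i, j] * x_t[j]
    for (j in seq_len(H)) ac <- ac + p$W[i, j] * (r[j] * h_prev[j])
    hc[i] <- if (activation == "relu") max(ac, 0) else tanh(ac)
    h[i] <- (1 - z[i]) * h_prev[i] + z[i] * hc[i]
  }
  h
}

# Full stacked path + linear head, scalar loops over layers and time.
oracle_path_forward <- function(x_seq, layers, V, cbias,
                                activation = "relu") {
  Tn <- length(x_seq)
  L <- length(layers)
  y <- numeric(Tn)
  hs <- lapply(layers, function(l) numeric(nrow(l$W)))
  for (t in seq_len(Tn)) {
    inp <- x_seq[t]
    for (l in seq_len(L)) {
      hs[[l]] <- oracle_gru_step(inp, hs[[l]], layers[[l]], activation)
      inp <- hs[[l]]
    }
    acc <- cbias
    for (i in seq_along(V)) acc <- acc + V[i] * hs[[L]][i]
    y[t] <- acc
  }
  y
}

# Sine evaluator independent of generate_voluntary().
oracle_sine <- function(a, f, phi, n, rate_hz) {
  out <- numeric(n)
  for (k in seq_len(n)) out[k] <- a * sin(2 * pi * f * (k - 1) / rate_hz + phi)
  out
}

rand_cell <- function(hidden, input = 1L, scale = 0.5) {
  m <- function(r, c) matrix(runif(r * c, -scale, scale), r, c)
  list(Ur = m(hidden, input), Wr = m(hidden, hidden),
       Uz = m(hidden, input), Wz = m(hidden, hidden),
       U = m(hidden, input), W = m(hidden, hidden),
       br = runif(hidden, -scale, scale), bz = runif(hidden, -scale, scale),
       bh = runif(hidden, -scale, scale))
}

rand_path <- function(n_layers, hidden, scale = 0.5) {
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers))
    layers[[l]] <- rand_cell(hidden, if (l == 1L) 1L else hidden, scale)
  list(layers = layers, V = runif(hidden, -scale, scale),
       c = runif(1, -0.1, 0.1))
}
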