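.act_code <- function(activation) {
  switch(match.arg(activation, c("relu", "tanh")), relu = 0L, tanh = 1L)
}

#' One GRU cell update
#'
#' Reference implementation of a single gated-recurrent-unit step:
#' \deqn{r = \sigma(U_r x + W_r h_{prev} + b_r)}
#' \deqn{z = \sigma(U_z x + W_z h_{prev} + b_z)}
#' \deqn{\tilde h = \mathrm{act}(U x + W (r \odot h_{prev}) + b_h)}
#' \deqn{h = (1 - z) \odot h_{prev} + z \odot \tilde h}
#' where \eqn{\sigma} is the logistic sigmoid, the reset gate `r`
#' controls how much old state enters the candidate, and the update
#' gate `z` controls how much the state moves toward the candidate.
#' The candidate activation is ReLU by default (with a `tanh` switch
#' for stability comparisons).
#'
#' This is the definition the compiled batched kernels implement; it is
#' exported so single steps can be inspected and cross-checked.
#'
#' @param x_t input vector for this timestep (length = input size).
#' @param h_prev hidden state vector from the previous timestep.
#' @param params list with matrices `Ur`, `Wr`, `Uz`, `Wz`, `U`, `W`
#'   (each `hidden x input` or `hidden x hidden`) and bias vectors
#'   `br`, `bz`, `bh`.
#' @param activation candidate activation, `"relu"` or `"tanh"`.
#' @return The updated hidden state vector `h_t`.
#' @examples
#' p <- gru_layer_params(1, 2)
#' gru_cell_step(0.3, c(0.1, -0.2), p)
#' @export
gru_cell_step <- function(x_t, h_prev, params, activation = "relu") {
  x_t <- as.numeric(x_t); h_prev <- as.numeric(h_prev)
  p <- params
  stopifnot(ncol(p$Ur) == length(x_t), ncol(p$Wr) == length(h_prev),
            nrow(p$W) == length(h_prev))
  r <- plogis(drop(p$Ur %*% x_t + p$Wr %*% h_prev) + p$br)
  z <- plogis(drop(p$Uz %*% x_t + p$Wz %*% h_prev) + p$bz)
  a <- drop(p$U %*% x_t + p$W %*% (r * h_prev)) + p$bh
  h_tilde <- if (activation == "relu") pmax(a, 0) else tanh(a)
  (1 - z) * h_prev + z * h_tilde
}

#' Initialize the weights of one GRU layer
#'
#' Matrices are drawn from `U(-1/sqrt(hidden), 1/sqrt(hidden))`; biases
#' start at zero.  Uses the global RNG.
#'
#' @param input_size number of inputs per timestep.
#' @param hidden_size number of hidden units.
#' @return A list with `Ur`, `Wr`, `Uz`, `Wz`, `U`, `W`, `br`, `bz`,
#'   `bh` (the per-gate input-to-hidden and hidden-to-hidden weights and
#'   biases).
#' @export
gru_layer_params <- function(input_size, hidden_size) {
  s <- 1 / sqrt(hidden_size)
  m <- function(r, c) matrix(runif(r * c, -s, s), r, c)
  list(Ur = m(hidden_size, input_size), Wr = m(hidden_size, hidden_size),
       Uz = m(hidden_size, input_size), Wz = m(hidden_size, hidden_size),
       U  = m(hidden_size, input_size), W  = m(hidden_size, hidden_size),
       br = numeric(hidden_size), bz = numeric(hidden_size),
       bh = numeric(hidden_size))
}

# Fresh parameters for one path: L stacked layers + linear head.
.path_params <- function(n_layers, hidden_size, input_size = 1L) {
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers))
    layers[[l]] <- gru_layer_params(if (l == 1L) input_size else hidden_size,
                                    hidden_size)
  s <- 1 / sqrt(hidden_size)
  list(layers = layers, V = runif(hidden_size, -s, s), c = 0)
}

.path_forward <- function(path, X, act, h0 = matrix(0, 0, 0),
                          return_hidden = FALSE) {
  cpp_path_forward(X, path$layers, path$V, path$c, h0, act, return_hidden)
}

#' Run the bidirectional network over measurement windows
#'
#' Produces the two per-timestep voluntary-component estimates: the
#' forward (online, predictive) path consumes samples in time order and
#' its output at index `t` depends only on samples `1..t`; the backward
#' (offline) path consumes the window in reverse and its output is
#' re-reversed to the input's index order, so its *early* indices are
#' the most refined.  The two paths share no weights and are never
#' mixed or averaged.
#'
#' @param object a fitted [tremornet()] model, or a raw parameter list
#'   with elements `forward` and `backward` (each `list(layers, V, c)`).
#' @param measurement numeric vector (one window) or a `T x B` matrix
#'   of windows in columns.
#' @param activation candidate activation (taken from the model when
#'   `object` is fitted).
#' @return For a vector input, a list of class `"network_output"` with
#'   `forward_estimate` and `backward_estimate` (both length `T`); for
#'   a matrix input, the same with `T x B` matrices.
#' @export
network_forward <- function(object, measurement, activation = NULL) {
  pars <- if (inherits(object, "tremornet"))
    list(forward = object$forward, backward = object$backward) else object
  if (is.null(activation))
    activation <- if (inherits(object, "tremornet"))
      object$config$activation else "relu"
  act <- .act_code(activation)
  vec_in <- is.null(dim(measurement))
  X <- if (vec_in) matrix(as.numeric(measurement), ncol = 1L)
       else as.matrix(measurement)
  if (nrow(X) < 2L) stop("window must contain at least 2 samples")
  if (any(!is.finite(X))) stop("measurement contains non-finite values")
  Tn <- nrow(X)
  fwd <- .path_forward(pars$forward, X, act)$y
  bwd <- .path_forward(pars$backward, X[Tn:1L, , drop = FALSE], act)$y
  bwd <- bwd[Tn:1L, , drop = FALSE]
  out <- list(forward_estimate = if (vec_in) drop(fwd) else fwd,
              backward_estimate = if (vec_in) drop(bwd) else bwd)
  class(out) <- "network_output"
  out
}

#' @export
print.network_output <- function(x, ...) {
  n <- NROW(x$forward_estimate)
  b <- NCOL(x$forward_estimate)
  cat(sprintf("<network_output> %d timesteps x %d window(s); forward (online) and backward (offline) estimates\n",
              n, b))
  invisible(x)
}
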