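#' Fit the bidirectional GRU tremor separator
#'
#' Trains a deep bidirectional recurrent network that maps a
#' tremor-contaminated \[0, 1\] measurement window to its voluntary
#' component, one estimate per timestep.  The architecture stacks
#' `n_layers` GRU layers per direction (layer `k` consumes the hidden
#' sequence of the same-direction layer `k - 1`; there is no mixing
#' matrix and no cross-talk between directions), followed by a linear
#' head per path.  The forward path is strictly causal and serves
#' online, predictive use; the backward path processes the window in
#' reverse time and serves offline use.
#'
#' Training minimizes the mean squared error between each path's output
#' and the *one-sample-advanced* ground-truth voluntary sequence
#' (shifted-target strategy): the network thereby learns to predict the
#' voluntary component one sample ahead (10 ms at 100 Hz) rather than
#' merely reconstruct it.  Both paths are trained against the same
#' shifted target, the backward path on the time-reversed window.
#' Optimization is ADAM (learning rate 0.0001 by default) over shuffled
#' minibatches, with global-norm gradient clipping; the returned
#' weights are those of the epoch with minimum validation loss.
#'
#' Gradients are evaluated in single precision by a compiled,
#' batch-fused backpropagation-through-time kernel; inference runs in
#' double precision.  With a fixed `seed` the whole loss history is
#' bit-reproducible.
#'
#' @param data a `"tremor_dataset"` from [build_dataset()] with
#'   nonempty `train` and `validation` splits.
#' @param hidden_size hidden units per layer (400 in the full-scale
#'   geometry; reduce for desk-scale runs).
#' @param n_layers stacked GRU layers per direction.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate ADAM learning rate.
#' @param activation candidate activation inside the GRU: `"relu"`
#'   (default) or `"tanh"`.
#' @param clip_norm global gradient-norm clip; `Inf` disables.
#' @param seed integer seed controlling initialization and batch
#'   shuffling.
#' @param verbose print per-epoch losses.
#' @return An object of class `"tremornet"`: a list with parameter sets
#'   `forward` and `backward` (each `list(layers, V, c)` at the
#'   best-validation epoch), `config`, `history` (data frame of
#'   per-epoch train and validation loss), `best_epoch`, and the
#'   matched `call`.  Supported methods: [predict.tremornet()],
#'   `print`, `summary`, `coef`, `plot`, `residuals`.
#' @examples
#' \donttest{
#' ds <- build_dataset(6, 6, window = 120, seed = 1)
#' fit <- tremornet(ds, hidden_size = 8, epochs = 3, seed = 1)
#' fit
#' }
#' @seealso [network_forward()], [predict_online()], [estimate_offline()]
#' @export
tremornet <- function(data, hidden_size = 400, n_layers = 4, epochs = 50,
                      batch_size = 64, learning_rate = 1e-4,
                      activation = c("relu", "tanh"), clip_norm = 5,
                      seed = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "tremor_dataset"))
  activation <- match.arg(activation)
  act <- .act_code(activation)
  if (!length(data$train)) stop("`data` has an empty training split")
  has_val <- length(data$validation) > 0L
  if (!has_val) stop("`data` has an empty validation split")
  if (!is.null(seed)) set.seed(seed)

  tr <- .split_matrices(data$train)
  va <- .split_matrices(data$validation)
  Tn <- nrow(tr$X); N <- ncol(tr$X)
  rev_t <- Tn:1L

  init_f <- .path_params(n_layers, hidden_size)
  init_b <- .path_params(n_layers, hidden_size)
  clip <- if (is.finite(clip_norm)) clip_norm else -1
  tf <- cpp_trainer_create(init_f$layers, init_f$V, init_f$c,
                           learning_rate, 0.9, 0.999, 1e-8, clip, act)
  tb <- cpp_trainer_create(init_b$layers, init_b$V, init_b$c,
                           learning_rate, 0.9, 0.999, 1e-8, clip, act)

  Xrev <- tr$X[rev_t, , drop = FALSE]
  Yrev <- tr$Y[rev_t, , drop = FALSE]
  vXrev <- va$X[rev_t, , drop = FALSE]
  vYrev <- va$Y[rev_t, , drop = FALSE]
  val_batches <- split(seq_len(ncol(va$X)),
                       ceiling(seq_len(ncol(va$X)) / batch_size))

  history <- data.frame(epoch = seq_len(epochs), train = NA_real_,
                        validation = NA_real_)
  best <- list(loss = Inf, forward = NULL, backward = NULL, epoch = NA)

  for (ep in seq_len(epochs)) {
    idx <- sample.int(N)
    batches <- split(idx, ceiling(seq_along(idx) / batch_size))
    tl <- 0
    for (b in batches) {
      lf <- cpp_trainer_step(tf, tr$X[, b, drop = FALSE],
                             tr$Y[, b, drop = FALSE])
      lb <- cpp_trainer_step(tb, Xrev[, b, drop = FALSE],
                             Yrev[, b, drop = FALSE])
      if (!is.finite(lf) || !is.finite(lb))
        stop(sprintf(paste0("training diverged at epoch %d (forward loss ",
                            "%g, backward loss %g); try a lower learning ",
                            "rate, a finite `clip_norm`, or activation ",
                            "= \"tanh\""), ep, lf, lb))
      tl <- tl + (lf + lb) / 2 * length(b)
    }
    vl <- 0
    for (b in val_batches) {
      vl <- vl + length(b) / 2 *
        (cpp_trainer_eval(tf, va$X[, b, drop = FALSE],
                          va$Y[, b, drop = FALSE]) +
         cpp_trainer_eval(tb, vXrev[, b, drop = FALSE],
                          vYrev[, b, drop = FALSE]))
    }
    history$train[ep] <- tl / N
    history$validation[ep] <- vl / ncol(va$X)
    if (history$validation[ep] < best$loss) {
      best$loss <- history$validation[ep]
      best$forward <- cpp_trainer_params(tf)
      best$backward <- cpp_trainer_params(tb)
      best$epoch <- ep
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  validation %.6f%s",
                      ep, history$train[ep], history$validation[ep],
                      if (best$epoch == ep) "  *" else ""))
  }

  structure(list(
    forward = list(layers = best$forward$layers, V = best$forward$V,
                   c = best$forward$c),
    backward = list(layers = best$backward$layers, V = best$backward$V,
                    c = best$backward$c),
    config = list(hidden_size = hidden_size, n_layers = n_layers,
                  window = Tn, rate_hz = attr(data, "rate_hz"),
                  epochs = epochs, batch_size = batch_size,
                  learning_rate = learning_rate, activation = activation,
                  clip_norm = clip_norm, seed = seed,
                  offset = attr(data, "offset")),
    history = history, best_epoch = best$epoch,
    call = match.call()), class = "tremornet")
}

#' @export
print.tremornet <- function(x, ...) {
  cfg <- x$config
  cat("Bidirectional GRU tremor separator\n")
  cat(sprintf("  %d layer(s) x %d hidden units per direction; %s candidate activation\n",
              cfg$n_layers, cfg$hidden_size, cfg$activation))
  cat(sprintf("  trained on %d-sample windows at %g Hz (shifted-target, one-sample-ahead)\n",
              cfg$window, cfg$rate_hz))
  cat(sprintf("  best validation MSE %.6f at epoch %d/%d\n",
              min(x$history$validation, na.rm = TRUE), x$best_epoch,
              cfg$epochs))
  invisible(x)
}

#' @export
summary.tremornet <- function(object, ...) {
  cfg <- object$config
  n_per_layer <- vapply(object$forward$layers, function(l)
    sum(vapply(l, length, 1L)), 1)
  structure(list(config = cfg,
                 n_parameters = 2 * (sum(n_per_layer) +
                                     length(object$forward$V) + 1),
                 history = object$history,
                 best_epoch = object$best_epoch),
            class = "summary.tremornet")
}

#' @export
print.summary.tremornet <- function(x, ...) {
  cfg <- x$config
  cat("Bidirectional GRU tremor separator\n")
  cat(sprintf("  layers: %d  hidden: %d  window: %d  activation: %s\n",
              cfg$n_layers, cfg$hidden_size, cfg$window, cfg$activation))
  cat(sprintf("  parameters: %s (both paths)\n",
              format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  ADAM lr %g, batch %d, %d epochs, clip %g, seed %s\n",
              cfg$learning_rate, cfg$batch_size, cfg$epochs, cfg$clip_norm,
              as.character(cfg$seed)))
  h <- x$history
  cat(sprintf("  loss: first epoch train %.6f -> last %.6f; best validation %.6f (epoch %d)\n",
              h$train[1L], h$train[nrow(h)],
              min(h$validation, na.rm = TRUE), x$best_epoch))
  invisible(x)
}

#' @export
coef.tremornet <- function(object, path = c("forward", "backward"), ...) {
  path <- match.arg(path)
  object[[path]]
}

#' @export
#' @importFrom graphics matplot legend
plot.tremornet <- function(x, ...) {
  h <- x$history
  matplot(h$epoch, cbind(h$train, h$validation), type = "l", lty = 1,
          col = c("grey40", "firebrick"), xlab = "epoch",
          ylab = "MSE (shifted target)", main = "Training history", ...)
  legend("topright", c("train", "validation"), lty = 1,
         col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Residuals of the fitted separator
#'
#' One-sample-ahead residuals of the forward (online) path against the
#' shifted targets of a dataset split.
#'
#' @param object a fitted [tremornet()].
#' @param data a `"tremor_dataset"`.
#' @param split which split to evaluate.
#' @param ... unused.
#' @return A `T x N` matrix of residuals (estimate minus target).
#' @export
residuals.tremornet <- function(object, data,
                                split = c("validation", "test", "train"),
                                ...) {
  split <- match.arg(split)
  segs <- data[[split]]
  if (!length(segs)) stop("split '", split, "' is empty")
  m <- .split_matrices(segs)
  out <- network_forward(object, m$X)
  out$forward_estimate - m$Y
}

#' Predict from a fitted tremor separator
#'
#' @param object a fitted [tremornet()].
#' @param newdata a numeric vector, a `T x B` matrix of windows, or a
#'   `"tremor_dataset"` split element list.
#' @param mode `"window"` runs both paths over each supplied window;
#'   `"online"` streams the forward path causally over a series of any
#'   length (one-sample-ahead estimates); `"offline"` stitches the
#'   backward path over a long series (see [estimate_offline()]).
#' @param advance window advance for `mode = "offline"`.
#' @param ... unused.
#' @return For `"window"`, a `"network_output"`; for `"online"` and
#'   `"offline"`, a numeric vector the length of the input series.
#' @export
predict.tremornet <- function(object, newdata,
                              mode = c("window", "online", "offline"),
                              advance = 50, ...) {
  mode <- match.arg(mode)
  if (is.list(newdata) && !is.null(newdata$measurement))
    newdata <- newdata$measurement
  switch(mode,
    window = network_forward(object, newdata),
    online = predict_online(object, newdata)$estimate,
    offline = estimate_offline(object, newdata, advance = advance))
}

#' Stream the forward path for online, one-sample-ahead prediction
#'
#' Processes samples causally: after consuming the sample at time `t`,
#' the returned estimate at position `t` is the network's prediction of
#' the voluntary component at `t + 1` (10 ms ahead at 100 Hz).  Hidden
#' state is carried in `state`, so a long stream can be fed in chunks;
#' feeding a window sample-by-sample gives exactly the same final
#' estimate as one batch call on the full window.
#'
#' @param object a fitted [tremornet()] or raw parameter list.
#' @param new_samples numeric vector of newly arrived samples.
#' @param state state returned by a previous call, or `NULL` to start.
#' @return A list with `estimate` (one value per new sample) and
#'   `state` (pass to the next call).
#' @export
predict_online <- function(object, new_samples, state = NULL) {
  pars <- if (inherits(object, "tremornet")) object$forward
          else object$forward
  act <- .act_code(if (inherits(object, "tremornet"))
    object$config$activation else "relu")
  new_samples <- as.numeric(new_samples)
  if (!length(new_samples)) stop("no samples supplied")
  if (any(!is.finite(new_samples)))
    stop("stream contains missing or non-finite samples")
  h0 <- if (is.null(state)) matrix(0, 0, 0) else state
  # the compiled kernel needs >= 1 step; feed the chunk as one T x 1 batch
  res <- cpp_path_forward(matrix(new_samples, ncol = 1L), pars$layers,
                          pars$V, pars$c, h0, act, FALSE)
  list(estimate = drop(res$y), state = res$h_final)
}

#' Offline voluntary-motion estimation by window stitching
#'
#' Slides a `window`-sample analysis window along the series with step
#' `advance` and keeps, from each window, the *first* `advance` samples
#' of the backward path's estimate — the refined end of the backward
#' recursion — concatenating the kept pieces.  The final window is
#' placed flush with the end of the series and contributes every sample
#' not already covered, so the output has exactly the input's length.
#'
#' @param object a fitted [tremornet()].
#' @param series numeric vector, at least one window long.
#' @param advance window step in samples (default 50, i.e. 0.5 s at
#'   100 Hz).
#' @param window analysis window length; defaults to the length the
#'   model was trained on.
#' @return Numeric vector of voluntary-component estimates,
#'   `length(series)` long.
#' @export
estimate_offline <- function(object, series, advance = 50, window = NULL) {
  stopifnot(inherits(object, "tremornet"))
  if (is.null(window)) window <- object$config$window
  series <- as.numeric(series)
  n <- length(series)
  if (n < window)
    stop("series (", n, " samples) is shorter than one analysis window (",
         window, ")")
  stopifnot(advance >= 1)
  starts <- seq.int(1L, n - window + 1L, by = advance)
  if (starts[length(starts)] != n - window + 1L)
    starts <- c(starts, n - window + 1L)
  # evaluate all windows in one batched call
  W <- vapply(starts, function(s) series[s:(s + window - 1L)],
              numeric(window))
  est <- network_forward(object, W)$backward_estimate
  est <- matrix(est, nrow = window)
  out <- numeric(n)
  covered <- 0L
  for (i in seq_along(starts)) {
    s <- starts[i]
    upto <- if (i == length(starts)) n else min(s + advance - 1L, n)
    if (upto <= covered) next
    from <- covered + 1L
    out[from:upto] <- est[(from - s + 1L):(upto - s + 1L), i]
    covered <- upto
  }
  out
}
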