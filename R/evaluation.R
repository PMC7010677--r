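#' Mean squared error between an estimate and the ground truth
#'
#' `MSE = mean((ground_truth - estimate)^2)` over the window.  On
#' pipeline data both signals already live on the \[0, 1\] measurement
#' scale, so this value is the "normalized MSE" reported throughout;
#' `relative = TRUE` additionally divides by the mean power of the
#' ground truth (an alternative normalization, provided for
#' comparability with conventions that scale by signal energy).
#'
#' @param estimate,ground_truth equal-length numeric vectors.
#' @param relative divide by `mean(ground_truth^2)`.
#' @return A nonnegative scalar.
#' @export
mse <- function(estimate, ground_truth, relative = FALSE) {
  if (length(estimate) != length(ground_truth))
    stop("`estimate` and `ground_truth` must have the same length")
  if (!length(estimate)) stop("empty input")
  out <- mean((ground_truth - estimate)^2)
  if (relative) out <- out / mean(ground_truth^2)
  out
}

#' Endpoint errors of the two network paths
#'
#' The operating points of the two paths sit at opposite ends of a
#' window: online use consumes the forward path's *last* sample (the
#' freshest prediction), offline use consumes the backward path's
#' *first* sample (the most refined end of the reversed recursion).
#' This returns the batch-mean squared error at those two indices.
#'
#' @param outputs a `"network_output"` whose estimates are `T x N`
#'   matrices (from [network_forward()] on a batch), or a list of
#'   single-window `"network_output"` objects.
#' @param targets matching targets: a `T x N` matrix or list of
#'   vectors.
#' @return Named numeric vector with `forward_last` and
#'   `backward_first`.
#' @export
endpoint_errors <- function(outputs, targets) {
  if (inherits(outputs, "network_output")) {
    fwd <- as.matrix(outputs$forward_estimate)
    bwd <- as.matrix(outputs$backward_estimate)
  } else {
    if (!length(outputs)) stop("empty batch")
    fwd <- vapply(outputs, function(o) as.numeric(o$forward_estimate),
                  numeric(length(outputs[[1L]]$forward_estimate)))
    bwd <- vapply(outputs, function(o) as.numeric(o$backward_estimate),
                  numeric(length(outputs[[1L]]$backward_estimate)))
  }
  tg <- if (is.list(targets))
    vapply(targets, as.numeric, numeric(nrow(fwd))) else as.matrix(targets)
  if (!all(dim(tg) == dim(fwd)))
    stop("`targets` do not match the outputs' dimensions")
  Tn <- nrow(fwd)
  c(forward_last = mean((fwd[Tn, ] - tg[Tn, ])^2),
    backward_first = mean((bwd[1L, ] - tg[1L, ])^2))
}

#' Sliding-FFT power spectral density
#'
#' Time-frequency power matrix computed by sliding an FFT window along
#' the series.  The defaults (window 50, overlap 45, i.e. hop 5) give
#' the smooth spectrotemporal display used for visual inspection of
#' measurement/estimate pairs.  Entries are squared FFT magnitudes
#' scaled to amplitude^2/Hz; the window function is rectangular unless
#' requested otherwise.
#'
#' @param series numeric vector, at least `window` samples.
#' @param rate_hz sampling rate in Hz.
#' @param window FFT window length in samples.
#' @param overlap samples shared by consecutive windows
#'   (`0 <= overlap < window`).
#' @param window_fn `"rectangular"` (default) or `"hann"`.
#' @return A matrix of class `"sliding_psd"` with one row per
#'   nonnegative frequency bin and `floor((N - window) / hop) + 1`
#'   columns, with attributes `freq` (Hz) and `time` (s, window
#'   centers).
#' @examples
#' x <- sin(2 * pi * 5 * (0:199) / 100)
#' p <- sliding_psd(x, 100)
#' dim(p)
#' @export
sliding_psd <- function(series, rate_hz = 100, window = 50, overlap = 45,
                        window_fn = c("rectangular", "hann")) {
  window_fn <- match.arg(window_fn)
  series <- as.numeric(series)
  n <- length(series)
  if (n < window) stop("series shorter than one FFT window")
  if (overlap < 0 || overlap >= window)
    stop("`overlap` must satisfy 0 <= overlap < window")
  hop <- window - overlap
  starts <- seq.int(1L, n - window + 1L, by = hop)
  wf <- if (window_fn == "hann")
    0.5 * (1 - cos(2 * pi * (seq_len(window) - 1) / (window - 1)))
  else rep(1, window)
  nb <- floor(window / 2) + 1L
  seg <- vapply(starts, function(s) series[s:(s + window - 1L)] * wf,
                numeric(window))
  P <- (Mod(stats::mvfft(seg))^2 / (rate_hz * sum(wf^2)))[seq_len(nb), ,
                                                          drop = FALSE]
  structure(P, class = "sliding_psd",
            freq = (seq_len(nb) - 1) * rate_hz / window,
            time = (starts - 1 + window / 2) / rate_hz)
}

#' @export
#' @importFrom graphics image
plot.sliding_psd <- function(x, ...) {
  image(attr(x, "time"), attr(x, "freq"), t(unclass(x)),
        xlab = "time (s)", ylab = "frequency (Hz)",
        main = "Sliding-FFT PSD", ...)
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness and kurtosis into the
#' omnibus statistic `K2 = Z1^2 + Z2^2`, chi-squared with 2 degrees of
#' freedom under normality (D'Agostino's skewness transformation and
#' the Anscombe–Glynn kurtosis transformation).  Used as the
#' per-frequency normality screen before the Z-test comparison of
#' spectral populations.
#'
#' @param x numeric vector, `n >= 20`.
#' @return A list with `statistic` (K2), `p.value`, and the component
#'   standard scores `z_skewness` and `z_kurtosis`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 20) stop("the omnibus test needs at least 20 observations")
  d <- x - mean(x)
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  if (m2 == 0) stop("constant sample")
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino (1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * asinh(Y / alpha)

  # kurtosis: Anscombe & Glynn (1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  denom <- 1 + xs * sqrt(2 / (A - 4))
  term <- sign(denom) * ((1 - 2 / A) / abs(denom))^(1 / 3)
  z2 <- (1 - 2 / (9 * A) - term) / sqrt(2 / (9 * A))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = pchisq(k2, 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2)
}

# Two-sample Z-test on means (unpaired, unequal-variance form).
.z_test <- function(x, y) {
  z <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  list(z = z, p.value = 2 * pnorm(-abs(z)))
}

#' Population-level spectral comparison of inputs and outputs
#'
#' Treats the FFT magnitude at each frequency bin as a population over
#' segments and compares the input population against the output
#' population frequency by frequency: a D'Agostino–Pearson normality
#' screen for each group, a two-sample Z-test for the difference of
#' means, and 95% confidence half-widths `1.96 * sd / sqrt(n)`.  The
#' 0 Hz bin is excluded from the report (its magnitude reflects the
#' constant measurement offset, not oscillatory content).
#'
#' @param inputs,outputs equal-size sets of equal-length sequences:
#'   `T x n` matrices (columns are segments) or lists of vectors;
#'   `n >= 20`.
#' @param rate_hz sampling rate in Hz.
#' @return An object of class `"spectral_summary"`: a list with
#'   `table` (data frame with columns `freq`, `mean_in`, `sd_in`,
#'   `ci_in`, `mean_out`, `sd_out`, `ci_out`, `p_normal_in`,
#'   `p_normal_out`, `p_value`) and `n`.
#' @export
spectral_population_compare <- function(inputs, outputs, rate_hz = 100) {
  as_mat <- function(x) if (is.list(x))
    vapply(x, as.numeric, numeric(length(x[[1L]]))) else as.matrix(x)
  X <- as_mat(inputs); Y <- as_mat(outputs)
  if (!all(dim(X) == dim(Y)))
    stop("`inputs` and `outputs` must hold equally many equal-length sequences")
  n <- ncol(X)
  if (n < 20) stop("need at least 20 sequences per group")
  Tn <- nrow(X)
  bins <- 2:(floor(Tn / 2) + 1L)   # exclude 0 Hz
  freq <- (bins - 1) * rate_hz / Tn
  Ain <- Mod(stats::mvfft(X))[bins, , drop = FALSE]
  Aout <- Mod(stats::mvfft(Y))[bins, , drop = FALSE]
  tab <- data.frame(
    freq = freq,
    mean_in = rowMeans(Ain), sd_in = apply(Ain, 1, sd),
    mean_out = rowMeans(Aout), sd_out = apply(Aout, 1, sd))
  tab$ci_in <- 1.96 * tab$sd_in / sqrt(n)
  tab$ci_out <- 1.96 * tab$sd_out / sqrt(n)
  tab$p_normal_in <- apply(Ain, 1, function(v) dagostino_pearson(v)$p.value)
  tab$p_normal_out <- apply(Aout, 1, function(v) dagostino_pearson(v)$p.value)
  tab$p_value <- vapply(seq_len(nrow(tab)), function(i)
    .z_test(Ain[i, ], Aout[i, ])$p.value, 1)
  structure(list(table = tab, n = n), class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  t <- x$table
  cat(sprintf("<spectral_summary> %d frequency bins, n = %d per group\n",
              nrow(t), x$n))
  band <- t$freq > 3
  cat(sprintf("  mean magnitude above 3 Hz: input %.4g, output %.4g (ratio %.1fx)\n",
              mean(t$mean_in[band]), mean(t$mean_out[band]),
              mean(t$mean_in[band]) / mean(t$mean_out[band])))
  cat(sprintf("  bins with p < 0.01: %d / %d\n",
              sum(t$p_value < 0.01), nrow(t)))
  invisible(x)
}

#' @export
#' @importFrom graphics lines polygon
plot.spectral_summary <- function(x, ...) {
  t <- x$table
  plot(t$freq, t$mean_in, type = "l", col = "firebrick",
       xlab = "frequency (Hz)", ylab = "FFT magnitude (mean, 95% CI)",
       ylim = range(0, t$mean_in + t$ci_in, t$mean_out + t$ci_out), ...)
  polygon(c(t$freq, rev(t$freq)),
          c(t$mean_in - t$ci_in, rev(t$mean_in + t$ci_in)),
          col = grDevices::adjustcolor("firebrick", 0.2), border = NA)
  lines(t$freq, t$mean_out, col = "steelblue")
  polygon(c(t$freq, rev(t$freq)),
          c(t$mean_out - t$ci_out, rev(t$mean_out + t$ci_out)),
          col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  legend("topright", c("input", "output"), lty = 1,
         col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Statistical comparison of separation methods
#'
#' Given paired per-segment error samples for two or more methods,
#' reports per-method mean normalized MSE with 95% confidence
#' intervals, a one-way ANOVA across methods, all pairwise two-sample
#' Z-tests (raw and Bonferroni-adjusted p-values; the published
#' comparison reports raw pairwise tests, so both are given, labeled),
#' and the percent improvement of the reference method over every
#' other: `(other_mean - ref_mean) / other_mean * 100`.
#'
#' @param errors_by_method named list of equal-length numeric vectors
#'   (>= 2 methods, >= 20 paired samples each).
#' @param reference method to compute improvements for; defaults to
#'   the first element.
#' @return An object of class `"method_comparison"`: a list with
#'   `summary` (data frame: method, n, mean, sd, ci half-width),
#'   `anova_p`, `pairwise` (data frame with raw and adjusted
#'   p-values), `improvement` (named vector, percent), `reference`.
#' @examples
#' set.seed(1)
#' e <- list(net = rnorm(50, 0.02, 0.005), bmflc = rnorm(50, 0.2, 0.05))
#' compare_methods(e)
#' @export
compare_methods <- function(errors_by_method, reference = NULL) {
  if (!is.list(errors_by_method) || length(errors_by_method) < 2L)
    stop("need at least two methods")
  nm <- names(errors_by_method)
  if (is.null(nm) || any(!nzchar(nm))) stop("methods must be named")
  lens <- vapply(errors_by_method, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("error samples must be paired: equal counts per method")
  if (lens[1L] < 20) stop("need at least 20 paired samples per method")
  if (is.null(reference)) reference <- nm[1L]
  if (!reference %in% nm) stop("unknown reference method: ", reference)

  n <- lens[1L]
  means <- vapply(errors_by_method, mean, 1)
  sds <- vapply(errors_by_method, sd, 1)
  summ <- data.frame(method = nm, n = n, mean = means, sd = sds,
                     ci = 1.96 * sds / sqrt(n), row.names = NULL)

  df <- data.frame(err = unlist(errors_by_method, use.names = FALSE),
                   method = factor(rep(nm, each = n), levels = nm))
  an <- stats::aov(err ~ method, data = df)
  anova_p <- summary(an)[[1L]][["Pr(>F)"]][1L]

  pairs <- utils::combn(nm, 2L)
  pw <- data.frame(a = pairs[1L, ], b = pairs[2L, ],
                   p_raw = apply(pairs, 2L, function(p)
                     .z_test(errors_by_method[[p[1L]]],
                             errors_by_method[[p[2L]]])$p.value))
  pw$p_bonferroni <- pmin(1, stats::p.adjust(pw$p_raw, "bonferroni"))

  others <- setdiff(nm, reference)
  improvement <- vapply(others, function(m)
    (means[[m]] - means[[reference]]) / means[[m]] * 100, 1)

  structure(list(summary = summ, anova_p = anova_p, pairwise = pw,
                 improvement = improvement, reference = reference),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, digits = 4, ...) {
  cat("Method comparison (normalized MSE)\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s mean %.6f  (95%% CI +/- %.6f, n = %d)\n",
                s$method[i], s$mean[i], s$ci[i], s$n[i]))
  cat(sprintf("  one-way ANOVA p = %.3g\n", x$anova_p))
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("  %s vs %s: p = %.3g (Bonferroni %.3g)\n",
                x$pairwise$a[i], x$pairwise$b[i],
                x$pairwise$p_raw[i], x$pairwise$p_bonferroni[i]))
  for (m in names(x$improvement))
    cat(sprintf("  improvement of %s over %s: %+.2f%%\n",
                x$reference, m, x$improvement[[m]]))
  invisible(x)
}
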