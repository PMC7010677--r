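#' Draw random voluntary-motion parameters
#'
#' The synthetic voluntary component of hand motion is a sinusoid
#' `a * sin(2 * pi * f * t + phi)` whose parameters are drawn
#' independently from uniform distributions: amplitude
#' `a ~ U(0, 0.25)`, frequency `f ~ U(0, 3)` Hz and phase
#' `phi ~ U(0, pi)`.  The 0–3 Hz support reflects the slow intended
#' movements expected from patients with movement disorders; everything
#' faster is attributed to tremor.
#'
#' Draws use R's global random number generator; call [set.seed()] for
#' reproducibility.
#'
#' @param n number of parameter triples to draw.
#' @return A data frame with columns `a`, `f`, `phi` and `n` rows.
#' @examples
#' set.seed(1)
#' sample_voluntary_params(3)
#' @export
sample_voluntary_params <- function(n = 1) {
  stopifnot(n >= 1)
  data.frame(a = runif(n, 0, 0.25),
             f = runif(n, 0, 3),
             phi = runif(n, 0, pi))
}

#' Generate a synthetic voluntary motion sequence
#'
#' Evaluates the voluntary-motion sinusoid on a sample grid:
#' `out[k] = a * sin(2 * pi * f * (k - 1) / rate_hz + phi)` for
#' `k = 1..n`.
#'
#' @param params a one-row data frame or list with elements `a`, `f`,
#'   `phi` (see [sample_voluntary_params()]).
#' @param n number of samples (>= 1).
#' @param rate_hz sampling rate in Hz.
#' @return Numeric vector of length `n`, bounded by `abs(a)`.
#' @export
generate_voluntary <- function(params, n, rate_hz = 100) {
  stopifnot(n >= 1, rate_hz > 0)
  k <- seq_len(n) - 1
  params$a * sin(2 * pi * params$f * k / rate_hz + params$phi)
}

#' Static tremor simulator settings
#'
#' Parameters of the surrogate generator used in place of clinical
#' static-tremor recordings (which are confidential and not
#' redistributable).  The simulated oscillation is nonstationary — its
#' amplitude follows a random walk and its instantaneous frequency
#' wanders slowly — with dominant power near `center_hz` (default 5 Hz,
#' where pathological tremor power accumulates across PD's typical
#' 4–6 Hz and ET's 4–8 Hz), band-limited to `band_hz` inside the 3–14 Hz
#' pathological tremor range, and min-max scaled to \[0, 0.5\].
#'
#' @param band_hz two-element vector `(low, high)` with
#'   `3 <= low < high <= 14`.
#' @param center_hz dominant frequency, inside `band_hz`.
#' @param amp_drift_rate standard deviation of the per-sample step of
#'   the log-amplitude random walk (relative units; 0 gives a constant
#'   envelope).
#' @param freq_jitter_hz amplitude of the slow (0.1 Hz) sinusoidal
#'   wander of the instantaneous frequency.
#' @param noise_floor standard deviation of the broadband noise added
#'   before band-pass filtering, relative to unit carrier amplitude.
#' @return An object of class `"tremor_sim_params"`.
#' @export
tremor_sim_params <- function(band_hz = c(4, 8), center_hz = 5,
                              amp_drift_rate = 0.02,
                              freq_jitter_hz = 0.5, noise_floor = 0.1) {
  stopifnot(length(band_hz) == 2L)
  if (!(band_hz[1L] >= 3 && band_hz[1L] < band_hz[2L] && band_hz[2L] <= 14))
    stop("`band_hz` must satisfy 3 <= low < high <= 14 ",
         "(the pathological tremor range)")
  if (center_hz < band_hz[1L] || center_hz > band_hz[2L])
    stop("`center_hz` must lie inside `band_hz`")
  stopifnot(amp_drift_rate >= 0, freq_jitter_hz >= 0, noise_floor >= 0)
  structure(list(band_hz = as.numeric(band_hz),
                 center_hz = as.numeric(center_hz),
                 amp_drift_rate = as.numeric(amp_drift_rate),
                 freq_jitter_hz = as.numeric(freq_jitter_hz),
                 noise_floor = as.numeric(noise_floor)),
            class = "tremor_sim_params")
}

#' @export
print.tremor_sim_params <- function(x, ...) {
  cat(sprintf(paste0("<tremor_sim_params> band %g-%g Hz, center %g Hz, ",
                     "amp drift %g, freq jitter %g Hz, noise %g\n"),
              x$band_hz[1L], x$band_hz[2L], x$center_hz,
              x$amp_drift_rate, x$freq_jitter_hz, x$noise_floor))
  invisible(x)
}

#' Simulate a static pathological tremor recording
#'
#' Synthesizes a nonstationary tremor-band oscillation: an
#' amplitude-modulated carrier (log-amplitude random walk) whose
#' instantaneous frequency wanders slowly around `center_hz`, plus
#' broadband noise, band-pass filtered to `band_hz` (zero-phase
#' Butterworth) and min-max scaled to \[0, 0.5\] per recording — the
#' same per-recording convention applied to clinical static tremor
#' before mixing.  This is a synthetic stand-in for clinic recordings,
#' matching their spectral placement and nonstationarity but making no
#' claim of clinical fidelity.
#'
#' @param n number of samples; at least `2 * rate_hz` (two seconds) so
#'   the spectrum is estimable.
#' @param rate_hz sampling rate in Hz.
#' @param params a [tremor_sim_params()] object.
#' @param seed optional integer; if given, seeds the global RNG before
#'   drawing so the sequence is reproducible in isolation.
#' @return Numeric vector of length `n` with `min == 0` and
#'   `max == 0.5`.
#' @examples
#' x <- simulate_static_tremor(2000, 100, seed = 7)
#' range(x)
#' @export
simulate_static_tremor <- function(n, rate_hz = 100,
                                   params = tremor_sim_params(),
                                   seed = NULL) {
  stopifnot(inherits(params, "tremor_sim_params"))
  if (n < 2 * rate_hz)
    stop("need at least 2 seconds of samples (n >= 2 * rate_hz)")
  if (!is.null(seed)) set.seed(seed)
  k <- seq_len(n) - 1
  tt <- k / rate_hz
  # slow frequency wander around the dominant frequency
  f_inst <- params$center_hz +
    params$freq_jitter_hz * sin(2 * pi * 0.1 * tt + runif(1, 0, 2 * pi))
  f_inst <- pmin(pmax(f_inst, params$band_hz[1L]), params$band_hz[2L])
  phase <- 2 * pi * cumsum(f_inst) / rate_hz + runif(1, 0, 2 * pi)
  # nonstationary envelope: log-amplitude random walk
  env <- exp(cumsum(rnorm(n, 0, params$amp_drift_rate)))
  x <- env * sin(phase) + rnorm(n, 0, params$noise_floor)
  bf <- signal::butter(2, params$band_hz / (rate_hz / 2), type = "pass")
  x <- signal::filtfilt(bf, x)
  scale_affine(x, 0, 0.5)$series
}

#' Mix voluntary and tremor components into a measurement
#'
#' The measurement model is additive.  The voluntary component lies in
#' \[-0.25, 0.25\] and the scaled tremor in \[0, 0.5\]; a fixed
#' `offset` of +0.25 is added to the voluntary component before
#' summation so the pseudo-synthesized measurement lands exactly in the
#' network's \[0, 1\] input range.  The offset is a known constant
#' carried with every segment, so the ground truth stays recoverable:
#' `measurement - offset - tremor == voluntary` exactly.
#'
#' @param voluntary numeric vector in \[-0.25, 0.25\].
#' @param tremor numeric vector in \[0, 0.5\], same length.
#' @param offset fixed shift applied to the voluntary component
#'   (default 0.25).
#' @return Numeric measurement vector in \[0, 1\].
#' @export
mix_components <- function(voluntary, tremor, offset = 0.25) {
  if (length(voluntary) != length(tremor))
    stop("`voluntary` and `tremor` must have the same length")
  tol <- 1e-9
  if (any(voluntary < -0.25 - tol | voluntary > 0.25 + tol))
    stop("`voluntary` must lie in [-0.25, 0.25]")
  if (any(tremor < -tol | tremor > 0.5 + tol))
    stop("`tremor` must lie in [0, 0.5]")
  voluntary + offset + tremor
}

#' Build a pseudo-synthesized action-tremor dataset
#'
#' Generates a labeled dataset for training and evaluating the
#' separator: each synthetic subject contributes one continuous
#' simulated static-tremor recording (independent per-subject seed, so
#' subjects differ in their tremor realization), cut into non-overlapping
#' windows; each window is mixed with a freshly drawn voluntary sinusoid
#' to form the measurement, and paired with its ground-truth voluntary
#' sequence and the one-sample-advanced training target used for
#' predictive (shifted-target) training.
#'
#' Subjects — not segments — are partitioned into train / validation /
#' test splits (largest-remainder rounding of `split_fracs`), so no
#' subject's tremor appears in two splits and no information leaks from
#' training to evaluation.
#'
#' @param n_subjects number of synthetic subjects (>= 5 so each split is
#'   nonempty at the default fractions).
#' @param segments_per_subject windows cut per subject.
#' @param window window length in samples (>= 2).
#' @param rate_hz sampling rate in Hz.
#' @param tremor a [tremor_sim_params()] object.
#' @param split_fracs train/validation/test fractions summing to 1.
#' @param stride window stride; defaults to `window` (no overlap).
#' @param offset voluntary offset used by [mix_components()].
#' @param seed optional master seed; the dataset is bit-reproducible for
#'   a fixed seed.
#' @return An object of class `"tremor_dataset"`: a list with elements
#'   `train`, `validation`, `test` (lists of labeled segments — each a
#'   list with `measurement`, `voluntary_gt`, `shifted_target`,
#'   `tremor`, `subject_id`, `offset`), plus attributes `window`,
#'   `rate_hz`, `offset`.
#' @examples
#' ds <- build_dataset(6, 4, window = 200, seed = 1)
#' ds
#' @export
build_dataset <- function(n_subjects = 30, segments_per_subject = 60,
                          window = 400, rate_hz = 100,
                          tremor = tremor_sim_params(),
                          split_fracs = c(train = 0.6, validation = 0.2,
                                          test = 0.2),
                          stride = window, offset = 0.25, seed = NULL) {
  stopifnot(n_subjects >= 5, window >= 2, segments_per_subject >= 1)
  if (abs(sum(split_fracs) - 1) > 1e-8)
    stop("`split_fracs` must sum to 1")
  if (length(split_fracs) != 3L)
    stop("`split_fracs` must give train, validation and test fractions")
  if (!is.null(seed)) set.seed(seed)

  subject_seeds <- sample.int(.Machine$integer.max, n_subjects)
  subject_ids <- sprintf("S%03d", seq_len(n_subjects))

  # largest-remainder apportionment of subjects to splits
  quota <- split_fracs * n_subjects
  counts <- floor(quota)
  rem <- n_subjects - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  split_of <- rep(c("train", "validation", "test"), times = counts)

  n_tremor <- max((segments_per_subject - 1L) * stride + window,
                  2 * rate_hz)

  make_subject <- function(s) {
    trem <- simulate_static_tremor(n_tremor, rate_hz, tremor,
                                   seed = subject_seeds[s])
    segs <- segment_series(trem, window, stride)
    segs <- segs[seq_len(min(length(segs), segments_per_subject))]
    lapply(segs, function(tseg) {
      p <- sample_voluntary_params(1)
      v <- generate_voluntary(p, window + 1L, rate_hz)
      list(measurement = mix_components(v[seq_len(window)], tseg, offset),
           voluntary_gt = v[seq_len(window)] + offset,
           shifted_target = v[2:(window + 1L)] + offset,
           tremor = tseg,
           subject_id = subject_ids[s],
           offset = offset)
    })
  }

  splits <- list(train = list(), validation = list(), test = list())
  for (s in seq_len(n_subjects)) {
    sp <- split_of[s]
    splits[[sp]] <- c(splits[[sp]], make_subject(s))
  }
  structure(splits, class = "tremor_dataset",
            window = window, rate_hz = rate_hz, offset = offset)
}

#' @export
print.tremor_dataset <- function(x, ...) {
  n_subj <- vapply(x, function(s)
    length(unique(vapply(s, `[[`, "", "subject_id"))), 1L)
  n_seg <- vapply(x, length, 1L)
  cat(sprintf("<tremor_dataset> window %d @ %g Hz, offset %g\n",
              attr(x, "window"), attr(x, "rate_hz"), attr(x, "offset")))
  for (nm in names(x))
    cat(sprintf("  %-10s %4d segments from %d subject(s)\n",
                nm, n_seg[[nm]], n_subj[[nm]]))
  invisible(x)
}

# Stack a split's fields into T x N matrices for the trainer.
.split_matrices <- function(segments) {
  list(X = vapply(segments, `[[`, numeric(length(segments[[1L]]$measurement)),
                  "measurement"),
       Y = vapply(segments, `[[`, numeric(length(segments[[1L]]$shifted_target)),
                  "shifted_target"))
}
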