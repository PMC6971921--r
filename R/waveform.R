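# Temporal alignment, extension to a common 1280 ms window, resampling at
# 10 ms, normalization by the C2-C3 average flow, and FFT harmonic
# analysis.
#
# Alignment is circular within the cardiac cycle and is applied before
# extension: the waveform is cardiac-periodic, so a cyclic shift is
# well-defined, whereas padding first would break periodicity. A circular
# shift changes only DFT phases, never magnitudes; the diastolic padding is
# the only step that can alter the magnitude spectrum.

#' Align station waveforms by the steepest descent at C2-C3
#'
#' Gating by pulse oximetry introduces an arbitrary subject-specific
#' temporal offset. The offset is estimated at the C2-C3 station as the
#' time of the most negative cyclic central-difference derivative of Q
#' (the steepest systolic descent), and every station of the subject is
#' circularly shifted by the same amount so that this instant maps to
#' t = 0. Relative delays between stations are preserved exactly.
#'
#' Ties in the derivative are broken toward the earliest sample; a flat
#' waveform (no unique descent anywhere) is an error.
#'
#' @param waveforms Named list of [flow_waveform()]s sharing one subject's
#'   cycle; must contain `ref`.
#' @param ref Reference station label, default `"C2-C3"`.
#' @return A list of class `aligned_waveforms`: `waveforms` (shifted),
#'   `shift_s` (the common shift in seconds), `shift_index`, `ref`.
#' @export
align_by_steepest_descent <- function(waveforms, ref = "C2-C3") {
  stopifnot(is.list(waveforms), length(waveforms) >= 1)
  if (!ref %in% names(waveforms))
    stop("reference station '", ref, "' missing")
  w0 <- waveforms[[ref]]
  d <- cyclic_derivative(w0$q, w0$times)
  if (diff(range(d)) < 1e-12)
    stop("flat waveform at ", ref, ": steepest descent undefined (all ",
         length(d), " samples tie)")
  idx <- which.min(d)  # first minimum = earliest time
  shifted <- lapply(waveforms, circular_shift, k = idx - 1L)
  structure(list(waveforms = shifted, shift_s = w0$times[idx],
                 shift_index = idx - 1L, ref = ref),
            class = "aligned_waveforms")
}

#' Cyclic central-difference derivative
#'
#' @param q Samples over one period (uniform grid).
#' @param times Sample times.
#' @return `dq/dt` by central differences with periodic wrap-around.
#' @export
cyclic_derivative <- function(q, times) {
  n <- length(q)
  dt <- times[2] - times[1]
  (q[c(2:n, 1)] - q[c(n, 1:(n - 1))]) / (2 * dt)
}

#' Circularly shift a waveform by k samples
#'
#' Rotates the samples so that old sample `k + 1` becomes the new t = 0
#' sample; the time axis is unchanged. `circular_shift(w, k)` followed by
#' `circular_shift(w, n - k)` restores the input.
#'
#' @param w A [flow_waveform()].
#' @param k Integer shift in samples (non-negative).
#' @return The shifted waveform.
#' @export
circular_shift <- function(w, k) {
  n <- length(w$q)
  k <- k %% n
  if (k > 0) w$q <- w$q[c((k + 1):n, 1:k)]
  w
}

#' Extend a waveform through diastole and resample on a 10 ms grid
#'
#' Resamples one aligned cardiac cycle onto a fixed window (default
#' 1280 ms at 10 ms, 128 samples) shared by all subjects, so spectra are
#' comparable across different cycle durations. Samples within the native
#' cycle are linearly interpolated; the tail beyond the last native sample
#' is filled with the final diastolic sample value (`pad = "hold"`,
#' default) or zeros (`pad = "zero"`). Hold-padding avoids the step
#' discontinuity zero-padding would inject, since late diastole is
#' near-steady.
#'
#' @param w A [flow_waveform()]; its cycle must fit in the window.
#' @param window_s Window length in seconds (default 1.28).
#' @param dt_s Resampling interval in seconds (default 0.01).
#' @param pad `"hold"` or `"zero"`.
#' @return A [flow_waveform()] on the grid `seq(0, window_s - dt_s, dt_s)`
#'   with the native `period` retained.
#' @export
extend_and_resample <- function(w, window_s = 1.28, dt_s = 0.01,
                                pad = c("hold", "zero")) {
  stopifnot(inherits(w, "flow_waveform"))
  pad <- match.arg(pad)
  if (w$period > window_s + 1e-9)
    stop(sprintf("cycle duration %.0f ms exceeds the %.0f ms window",
                 1000 * w$period, 1000 * window_s))
  grid <- seq(0, window_s - dt_s, by = dt_s)
  t_last <- w$times[length(w$times)]
  inside <- grid <= t_last + 1e-12
  qr <- numeric(length(grid))
  qr[inside] <- approx(w$times, w$q, xout = grid[inside], rule = 2)$y
  qr[!inside] <- if (pad == "hold") w$q[length(w$q)] else 0
  flow_waveform(times = grid, q = qr, period = w$period,
                station = w$station, z_mm = w$z_mm, a_cs = w$a_cs)
}

#' Resample every station of an aligned set
#'
#' Applies [extend_and_resample()] to each station and stores the result
#' (plus a station-by-time matrix) on the set.
#'
#' @param aw An `aligned_waveforms` object.
#' @inheritParams extend_and_resample
#' @return The set with elements `resampled` (named list), `grid`, and
#'   `Q` (matrix, stations in rows).
#' @export
resample_aligned <- function(aw, window_s = 1.28, dt_s = 0.01,
                             pad = c("hold", "zero")) {
  stopifnot(inherits(aw, "aligned_waveforms"))
  pad <- match.arg(pad)
  aw$resampled <- lapply(aw$waveforms, extend_and_resample,
                         window_s = window_s, dt_s = dt_s, pad = pad)
  aw$grid <- aw$resampled[[1]]$times
  aw$Q <- do.call(rbind, lapply(aw$resampled, `[[`, "q"))
  rownames(aw$Q) <- names(aw$resampled)
  aw
}

#' Normalize a subject's waveforms by the C2-C3 average flow
#'
#' Divides every station's flow by the subject's C2-C3 average flow-rate
#' magnitude, making the waveforms dimensionless and emphasizing shape over
#' amplitude. "Average flow rate" is taken as the time-mean of |Q| over
#' the native cycle (`normalizer = "mean_abs"`, default); the mean systolic
#' magnitude (`"peak"`) and the stroke volume per unit time (`"stroke"`,
#' mean of the rectified caudal flow) are available alternatives.
#'
#' @param aw An `aligned_waveforms` object, resampled via
#'   [resample_aligned()].
#' @param normalizer One of `"mean_abs"`, `"peak"`, `"stroke"`.
#' @return The set with `resampled`/`Q` rescaled, and `normalizer_value`
#'   recorded.
#' @export
normalize_by_c23 <- function(aw, normalizer = c("mean_abs", "peak", "stroke")) {
  stopifnot(inherits(aw, "aligned_waveforms"), !is.null(aw$resampled))
  normalizer <- match.arg(normalizer)
  q0 <- aw$waveforms[[aw$ref]]$q
  val <- switch(normalizer,
                mean_abs = mean(abs(q0)),
                peak = abs(min(q0)),
                stroke = mean(pmax(-q0, 0)))
  if (val < 1e-12)
    stop("zero normalizer at ", aw$ref,
         " (near-zero flow should be excluded upstream)")
  aw$resampled <- lapply(aw$resampled, function(w) { w$q <- w$q / val; w })
  aw$Q <- aw$Q / val
  aw$normalizer <- normalizer
  aw$normalizer_value <- val
  aw
}

#' Harmonic (FFT) spectrum of a resampled waveform
#'
#' Discrete Fourier transform of the 128-sample windowed waveform, reported
#' at harmonics 1..7 of the fixed window (bin k corresponds to
#' k / 1.28 s = k * 0.781 Hz, not to the subject's own cardiac frequency).
#' Magnitudes use the one-sided 2/N scaling, so a pure sinusoid of
#' amplitude a on bin k yields magnitude a at harmonic k.
#'
#' @param w A [flow_waveform()] on the common grid, or a plain numeric
#'   vector of samples.
#' @param n_harmonics Number of harmonics to report (default 7).
#' @return A data.frame `harmonic`, `magnitude`, `phase` (radians).
#' @export
harmonic_spectrum <- function(w, n_harmonics = 7) {
  q <- if (inherits(w, "flow_waveform")) w$q else as.numeric(w)
  n <- length(q)
  stopifnot(n > 2 * n_harmonics)
  X <- fft(q)
  k <- seq_len(n_harmonics) + 1L
  data.frame(harmonic = seq_len(n_harmonics),
             magnitude = 2 * Mod(X[k]) / n,
             phase = Arg(X[k]))
}
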