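# Alignment, extension/resampling, normalization, harmonic analysis.

test_that("steepest descent of -sin(2 pi t / T) sits at t = 0", {
  w <- sine_waveform(n = 32, amp = -1, station = "C2-C3")
  aw <- align_by_steepest_descent(list("C2-C3" = w))
  expect_equal(aw$shift_s, 0)
  expect_equal(aw$waveforms[["C2-C3"]]$q, w$q)
})

test_that("a known circular shift is recovered and undone exactly", {
  n <- 32; period <- 0.96; dt <- period / n
  w <- sine_waveform(n = n, amp = -1, station = "C2-C3")
  k <- round(0.120 / dt)  # 120 ms = 4 samples at 30 ms
  ws <- circular_shift(w, n - k)  # descent now at t = +120 ms
  aw <- align_by_steepest_descent(list("C2-C3" = ws))
  expect_equal(aw$shift_s, 0.120)
  expect_equal(aw$waveforms[["C2-C3"]]$q, w$q, tolerance = 1e-12)

  # round trip: align then shift back restores the input bit-for-bit
  undone <- circular_shift(aw$waveforms[["C2-C3"]], n - aw$shift_index)
  expect_identical(undone$q, ws$q)
})

test_that("the common shift preserves relative delays between stations", {
  n <- 32
  w1 <- sine_waveform(n = n, amp = -1, station = "C2-C3")
  w2 <- circular_shift(sine_waveform(n = n, amp = -1, station = "T4-T5"), n - 3)
  shifted <- lapply(list("C2-C3" = w1, "T4-T5" = w2), circular_shift, k = 7)
  aw <- align_by_steepest_descent(shifted)
  d0 <- which.min(w2$q) - which.min(w1$q)
  d1 <- which.min(aw$waveforms[["T4-T5"]]$q) -
    which.min(aw$waveforms[["C2-C3"]]$q)
  expect_equal(d1 %% n, d0 %% n)
})

test_that("flat reference waveforms and missing stations are errors", {
  flat <- flow_waveform((0:9) / 10, rep(0, 10), 1)
  expect_error(align_by_steepest_descent(list("C2-C3" = flat)), "flat")
  expect_error(align_by_steepest_descent(list("FM" = flat)), "missing")
})

test_that("extension pads diastole with the terminal sample on a 128-point grid", {
  # constant zero, T = 1 s -> 128 zeros
  w0 <- flow_waveform((0:19) / 20, rep(0, 20), 1)
  r0 <- extend_and_resample(w0)
  expect_length(r0$q, 128)
  expect_true(all(r0$q == 0))

  # T = 1280 ms: pure resample, no padding
  n <- 64
  w1 <- flow_waveform((0:(n - 1)) * 1.28 / n, sin(2 * pi * (0:(n - 1)) / n),
                      1.28)
  r1 <- extend_and_resample(w1)
  expect_equal(r1$q[1:10], sin(2 * pi * r1$times[1:10] / 1.28),
               tolerance = 5e-3)  # linear-interp error only

  # T = 1 s with final sample 0.2 -> samples at 1000..1270 ms all 0.2
  q <- c(seq(-1, 0.4, length.out = 19), 0.2)
  w2 <- flow_waveform((0:19) / 20, q, 1)
  r2 <- extend_and_resample(w2)
  expect_true(all(r2$q[r2$times >= 0.999] == 0.2))
  r2z <- extend_and_resample(w2, pad = "zero")
  expect_true(all(r2z$q[r2z$times >= 0.999] == 0))

  expect_error(extend_and_resample(flow_waveform((0:9) * 0.14, rep(0, 10), 1.4)),
               "exceeds")
})

test_that("normalization by the C2-C3 average flow is scale-invariant", {
  n <- 32
  mk <- function(amp, st) sine_waveform(n = n, amp = amp, station = st)
  aw <- align_by_steepest_descent(list("C2-C3" = mk(-2, "C2-C3"),
                                       "T4-T5" = mk(-1, "T4-T5")))
  aw <- resample_aligned(aw)
  nz <- normalize_by_c23(aw)
  # self-normalization: time-mean |Q| of the reference over its cycle is 1
  expect_equal(mean(abs(aw$waveforms[["C2-C3"]]$q / nz$normalizer_value)), 1,
               tolerance = 1e-12)
  # station at half the reference amplitude -> normalized mean |Q| = 0.5
  expect_equal(mean(abs(aw$waveforms[["T4-T5"]]$q / nz$normalizer_value)), 0.5,
               tolerance = 1e-12)

  # doubling every flow leaves the normalized set unchanged
  aw2 <- align_by_steepest_descent(list("C2-C3" = mk(-4, "C2-C3"),
                                        "T4-T5" = mk(-2, "T4-T5")))
  nz2 <- normalize_by_c23(resample_aligned(aw2))
  expect_equal(nz2$Q, nz$Q, tolerance = 1e-12)
})

test_that("harmonic magnitudes are exact on bin-aligned sinusoids", {
  grid <- seq(0, 1.27, by = 0.01)
  q2 <- sin(2 * pi * 2 * grid / 1.28 + 0.4)  # bin 2, amplitude 1
  sp <- harmonic_spectrum(q2)
  expect_equal(sp$magnitude[2], 1, tolerance = 1e-12)
  expect_lt(max(sp$magnitude[-2]), 1e-12)

  expect_true(all(harmonic_spectrum(rep(0, 128))$magnitude == 0))

  q13 <- sin(2 * pi * grid / 1.28) + 0.4 * sin(2 * pi * 3 * grid / 1.28)
  sp13 <- harmonic_spectrum(q13)
  expect_equal(sp13$magnitude[c(1, 3)], c(1, 0.4), tolerance = 1e-12)
  expect_lt(max(sp13$magnitude[c(2, 4:7)]), 1e-12)
})

test_that("Parseval holds for zero-mean bin-aligned signals", {
  grid <- seq(0, 1.27, by = 0.01)
  q <- 1.3 * sin(2 * pi * 2 * grid / 1.28 + 0.2) +
    0.7 * sin(2 * pi * 5 * grid / 1.28 - 1) +
    0.2 * sin(2 * pi * 7 * grid / 1.28 + 2.2)
  sp <- harmonic_spectrum(q)
  # time-domain power = sum a_k^2 / 2 over the occupied bins
  expect_equal(sum(sp$magnitude^2) / 2, mean(q^2), tolerance = 1e-12)
})

test_that("circular shifts change harmonic phases but never magnitudes", {
  set.seed(11)
  grid <- seq(0, 1.27, by = 0.01)
  q <- as.numeric(2 * sin(2 * pi * grid / 1.28) +
                    rnorm(1) * sin(2 * pi * 4 * grid / 1.28 + 1))
  w <- flow_waveform(grid, q, 1.28)
  m0 <- harmonic_spectrum(w)$magnitude
  for (k in c(1, 17, 63, 100)) {
    expect_equal(harmonic_spectrum(circular_shift(w, k))$magnitude, m0,
                 tolerance = 1e-12)
  }
})
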