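# Phantom and cohort generator.

test_that("voxelized annulus recovers the closed-form SSS area", {
  spec <- annulus_spec(0.4, 0.8, voxel_mm = 0.4)
  seg <- make_phantom_geometry(spec)
  sl <- extract_slice_geometry(seg, 10)
  a_true <- pi * (0.8^2 - 0.4^2)  # 1.5080 cm^2
  expect_lt(abs(sl$a_cs / a_true - 1), 0.02)
})

test_that("constant cord knots give a constant cord area along z", {
  spec <- annulus_spec(0.4, 0.8, voxel_mm = 0.4, length_mm = 30)
  seg <- make_phantom_geometry(spec)
  areas <- vapply(c(0, 10, 20, 30),
                  function(z) extract_slice_geometry(seg, z)$a_c, 0)
  expect_lt(diff(range(areas)) / mean(areas), 0.01)
})

test_that("finer voxels reduce the worst-case dura discretization error", {
  # area error alone is already at the quantization noise floor (~0.1%)
  # and fluctuates; the combined area/perimeter error decreases reliably
  err <- vapply(c(0.8, 0.4), function(h) {
    sl <- extract_slice_geometry(
      make_phantom_geometry(annulus_spec(0.4, 0.8, voxel_mm = h,
                                         length_mm = 4)), 2)
    max(abs(sl$a_d / (pi * 0.8^2) - 1), abs(sl$p_d / (2 * pi * 0.8) - 1))
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("phantom_spec rejects geometries where the dura does not clear the cord", {
  expect_error(
    phantom_spec(length_mm = 100,
                 cord_radius_knots = cbind(c(0, 100), c(0.5, 0.5)),
                 dura_radius_knots = cbind(c(0, 100), c(0.6, 0.4)),
                 cord_aspect = 1, dura_aspect = 1),
    "dura radius must exceed"
  )
})

test_that("synthesized waveforms have exactly zero mean and expected extrema", {
  w1 <- synthesize_waveform(waveform_spec(period = 1, harmonic_amplitudes = 1,
                                          harmonic_phases = 0), n_phases = 30)
  expect_equal(mean(w1$q), 0, tolerance = 1e-14)
  expect_lt(abs(min(w1$q) - (-1)), 0.01)  # sampling misses the trough by <cos(pi/30)

  w0 <- synthesize_waveform(waveform_spec(harmonic_amplitudes = c(0, 0),
                                          harmonic_phases = c(0, 0)))
  expect_true(all(w0$q == 0))

  w2 <- synthesize_waveform(waveform_spec(harmonic_amplitudes = c(1.5, 0.5),
                                          harmonic_phases = c(0.3, 1.1)))
  expect_lte(max(abs(w2$q)), 2.0)

  # zero-mean property across random specs
  set.seed(42)
  for (i in 1:20) {
    ws <- waveform_spec(period = runif(1, 0.6, 1.2),
                        harmonic_amplitudes = runif(3, 0, 3),
                        harmonic_phases = runif(3, 0, 2 * pi))
    expect_equal(mean(synthesize_waveform(ws, 30)$q), 0, tolerance = 1e-13)
  }
})

test_that("noise-free velocity series integrates back to the delayed prescribed flow", {
  spec <- annulus_spec(0.4, 0.8, voxel_mm = 0.4, length_mm = 200,
                       noise_sd = 0, pwv_true = 400)
  ser <- make_pcmri_series(spec, 150)
  w <- integrate_flow(ser)
  peak <- max(abs(ser$q_true))
  expect_lt(max(abs(w$q - ser$q_true)) / peak, 0.03)
})

test_that("infinite wave speed gives identical waveforms at all stations", {
  spec <- annulus_spec(noise_sd = 0, pwv_true = Inf, length_mm = 200,
                       amplitude_decay = 1)
  q1 <- make_pcmri_series(spec, 0)$q_true
  q2 <- make_pcmri_series(spec, 180)$q_true
  expect_equal(q1, q2)
})

test_that("velocities beyond the VENC limit wrap around", {
  expect_equal(venc_wrap_velocity(12, 10), -8)
  expect_equal(venc_wrap_velocity(-12, 10), 8)
  expect_equal(venc_wrap_velocity(c(0, 9.99, 10), 10), c(0, 9.99, -10))
  # a series whose prescribed peak velocity exceeds VENC shows aliased samples
  ws <- waveform_spec(period = 1, harmonic_amplitudes = 12 * pi * (0.8^2 - 0.4^2),
                      harmonic_phases = 0)
  spec <- annulus_spec(noise_sd = 0, length_mm = 10, waveform = ws,
                       amplitude_decay = 1, pwv_true = 1e9)
  ser <- make_pcmri_series(spec, 0, venc_wrap = TRUE)
  v_peak <- ser$v[which.min(abs(ser$times - 0.25)), , ][ser$mask]
  expect_lt(max(abs(v_peak - (-8))), 0.35)  # 12 cm/s wraps to ~-8 (voxelized A)
})

test_that("cohorts are deterministic in the seed and zero jitter collapses a group", {
  gp <- list(a = list(), b = list(amplitude_scale = 0.5))
  c1 <- make_cohort(2, gp, seed = 7, imaging = FALSE)
  c2 <- make_cohort(2, gp, seed = 7, imaging = FALSE)
  expect_identical(c1, c2)

  c0 <- make_cohort(3, list(g = list()), seed = 3, imaging = FALSE,
                    jitter = list(radius = 0, amplitude = 0, pwv = 0,
                                  period = 0))
  specs <- lapply(c0$subjects, `[[`, "spec")
  expect_identical(specs[[1]], specs[[2]])
  expect_identical(specs[[1]], specs[[3]])
})

test_that("an amplitude-scaled group recovers the prescribed peak-flow ratio", {
  coh <- make_cohort(10, list(a = list(), b = list(amplitude_scale = 0.84)),
                     seed = 5, imaging = FALSE)
  peak <- vapply(coh$subjects, function(s)
    abs(min(synthesize_waveform(s$spec$waveform, 30)$q)), 0)
  grp <- vapply(coh$subjects, `[[`, "", "group")
  ratio <- mean(peak[grp == "b"]) / mean(peak[grp == "a"])
  # MC standard error of the ratio at n = 10 and 12% amplitude jitter ~ 0.045
  expect_lt(abs(ratio - 0.84), 3 * 0.045)
})
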