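# Spinal flow interpolation and hydrodynamic profiles.

make_two_station_set <- function(q1, q2, z1 = 0, z2 = 100, n = 16,
                                 period = 1.28) {
  tt <- seq(0, period - period / n, length.out = n)
  list(
    A = flow_waveform(tt, q1, period, station = "A", z_mm = z1),
    B = flow_waveform(tt, q2, period, station = "B", z_mm = z2)
  )
}

test_that("interpolating identical waveforms reproduces them at every z", {
  q <- sin(2 * pi * (0:15) / 16)
  wfs <- make_two_station_set(q, q)
  geom <- constant_geometry(0:100)
  stf <- interpolate_flow_along_spine(wfs, geom)
  # within the station span every z carries the station waveform
  inside <- stf$z_mm <= 100
  expect_true(all(apply(stf$Q[inside, ], 1, function(r) max(abs(r - q))) < 1e-12))
})

test_that("interpolation is linear between stations and zero at the sac end", {
  q1 <- rep(-2, 16); q2 <- rep(0, 16)
  wfs <- make_two_station_set(q1, q2)
  geom <- constant_geometry(0:150)  # sac at 150, stations at 0 and 100
  stf <- interpolate_flow_along_spine(wfs, geom)
  expect_equal(stf$Q[stf$z_mm == 50, 1], -1)          # midpoint
  expect_equal(stf$Q[stf$z_mm == 150, ], rep(0, 16))  # closed sac
  expect_error(interpolate_flow_along_spine(wfs["A"], geom))
})

test_that("interpolated systolic peaks follow the generator's amplitude decay", {
  spec <- phantom_spec(noise_sd = 0)
  subj <- phantom_subject(spec)
  s <- analyze_subject(subj, details = TRUE)
  stf <- attr(s, "details")$stf
  zq <- c(75, 160, 290, 410)  # off-station positions within the span
  q0 <- abs(min(stf$Q[stf$z_mm == 0, ]))
  for (z in zq) {
    expected <- q0 * spec$amplitude_decay^z
    got <- abs(stf$q_sys[stf$z_mm == z])
    expect_lt(abs(got / expected - 1), 0.03)
  }
})

test_that("Reynolds profile matches hand arithmetic and is linear in flow", {
  geom <- constant_geometry(0:10, a_cs = 1.5, d_h = 0.8)
  stf <- fake_stf(0:10, t_sys = rep(0.1, 11))
  stf$q_sys <- rep(-1, 11)
  re <- reynolds_profile(stf, geom, nu = 0.007)
  expect_equal(re$re, rep(0.8 / (0.007 * 1.5), 11), tolerance = 1e-9)  # 76.19
  expect_true(all(re$laminar))

  stf$q_sys <- rep(0, 11)
  expect_equal(reynolds_profile(stf, geom, nu = 0.007)$re, rep(0, 11))

  stf$q_sys <- rep(-2, 11)
  expect_equal(reynolds_profile(stf, geom, nu = 0.007)$re,
               2 * re$re, tolerance = 1e-12)
})

test_that("Womersley number follows both frequency conventions exactly", {
  geom <- constant_geometry(0:5, d_h = 1)
  a_paper <- womersley_profile(geom, period = 1, nu = 0.007,
                               convention = "literature")
  expect_equal(a_paper$alpha, rep(sqrt(2 / 0.007), 6), tolerance = 1e-9)
  a_ang <- womersley_profile(geom, period = 1, nu = 0.007)
  expect_equal(a_ang$alpha, rep(sqrt(2 * pi / 0.007), 6), tolerance = 1e-9)

  geom2 <- constant_geometry(0:5, d_h = 2)
  expect_equal(womersley_profile(geom2, 1, 0.007)$alpha, 2 * a_ang$alpha)
  expect_error(womersley_profile(geom, 1, 0.007, convention = "radial"))
})

test_that("velocity profiles divide flow by local SSS area, signed", {
  geom <- constant_geometry(0:10, a_cs = 1.5)
  stf <- fake_stf(0:10, t_sys = rep(0.1, 11))
  stf$q_sys <- rep(-1.5, 11); stf$q_dia <- rep(0.75, 11)
  vp <- velocity_profiles(stf, geom)
  expect_equal(vp$u_sys, rep(-1, 11))
  expect_equal(vp$u_dia, rep(0.5, 11))

  geom2 <- constant_geometry(0:10, a_cs = 0.75)
  expect_equal(velocity_profiles(stf, geom2)$u_sys, rep(-2, 11))
})

test_that("PWV equals 1/slope on exact linear arrival times", {
  z <- 0:400
  stf <- fake_stf(z, t_sys = (z / 10) / 400)  # z in cm over 400 cm/s
  fit <- pulse_wave_velocity(stf)
  expect_equal(fit$pwv_cm_s, 400, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # transposed regression agrees on noise-free data
  expect_equal(pulse_wave_velocity(stf, fit = "z_on_t")$pwv_cm_s, 400,
               tolerance = 1e-9)
})

test_that("identical arrival times raise the infinite-PWV flag", {
  stf <- fake_stf(0:100, t_sys = rep(0.12, 101))
  fit <- pulse_wave_velocity(stf)
  expect_true(fit$infinite)
  expect_identical(fit$pwv_cm_s, Inf)
})

test_that("non-pulsatile positions are excluded from the PWV fit", {
  z <- 0:200
  t_sys <- (z / 10) / 300
  t_sys[z > 150] <- 0  # corrupted tail ...
  p2p <- rep(1, 201); p2p[z > 150] <- 0.01  # ... but below the threshold
  stf <- fake_stf(z, t_sys)
  stf$p2p <- p2p
  stf$station_z_mm <- c(0, 200)
  fit <- pulse_wave_velocity(stf)
  expect_equal(fit$pwv_cm_s, 300, tolerance = 1e-9)
  expect_equal(fit$n, sum(z <= 150))
  expect_error(pulse_wave_velocity(fake_stf(0:1, c(0, 0.1))), "fewer than 3")
})

test_that("PWV is recovered within 5% on a noise-free phantom", {
  subj <- phantom_subject(phantom_spec(noise_sd = 0, pwv_true = 475))
  s <- analyze_subject(subj, details = TRUE)
  pwv <- attr(s, "details")$hydro$pwv$pwv_cm_s
  expect_lt(abs(pwv / 475 - 1), 0.05)
})
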