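# Shared fixtures, built in code at test time.

# Constant-radius circular annulus phantom (cord R_c, dura R_d, in cm).
annulus_spec <- function(r_c = 0.4, r_d = 0.8, voxel_mm = 0.4,
                         length_mm = 20, ...) {
  phantom_spec(
    length_mm = length_mm,
    cord_radius_knots = cbind(c(0, length_mm), c(r_c, r_c)),
    dura_radius_knots = cbind(c(0, length_mm), c(r_d, r_d)),
    cord_aspect = 1, dura_aspect = 1,
    voxel_size_mm = c(voxel_mm, voxel_mm, 1),
    ...
  )
}

# A sampled sinusoidal waveform  Q(t) = amp * sin(2 pi t / T + phase).
sine_waveform <- function(n = 32, period = 0.96, amp = 1, phase = 0,
                          station = NA_character_, z_mm = NA_real_,
                          a_cs = NA_real_) {
  tt <- (seq_len(n) - 1) * period / n
  flow_waveform(times = tt, q = amp * sin(2 * pi * tt / period + phase),
                period = period, station = station, z_mm = z_mm,
                a_cs = a_cs)
}

# Minimal geometry profile with constant slice values, for the pure
# arithmetic layers (Reynolds/Womersley/velocity/PWV) that only read the
# slice table.
constant_geometry <- function(z_mm, a_cs = 1.5, d_h = 0.8, a_c = 0.5,
                              p_c = 2, p_d = 5) {
  n <- length(z_mm)
  slices <- data.frame(
    z_mm = z_mm, z_norm = z_mm / max(z_mm),
    a_c = rep(a_c, n), a_d = rep(a_c + a_cs, n), a_cs = rep(a_cs, n),
    p_c = rep(p_c, n), p_d = rep(p_d, n), p_cs = rep(p_c + p_d, n),
    d_h = rep(d_h, n), missing = FALSE)
  dz <- if (n > 1) z_mm[2] - z_mm[1] else 1
  structure(
    list(slices = slices,
         v_c = sum(slices$a_c) * dz / 10, v_d = sum(slices$a_d) * dz / 10,
         v_cs = sum(slices$a_cs) * dz / 10,
         sa_c = sum(slices$p_c) * dz / 10, sa_d = sum(slices$p_d) * dz / 10,
         sa_cs = sum(slices$p_cs) * dz / 10,
         length_mm = max(z_mm), spacing_mm = dz),
    class = "geometry_profile")
}

# Hand-built spatio-temporal flow with prescribed arrival times, for
# exercising the PWV fit in isolation.
fake_stf <- function(z_mm, t_sys, p2p = 1, station_z = range(z_mm)) {
  structure(
    list(z_mm = z_mm, z_norm = z_mm / max(z_mm), times = NULL, Q = NULL,
         q_sys = rep(-1, length(z_mm)), t_sys = t_sys,
         q_dia = rep(1, length(z_mm)), t_dia = t_sys,
         p2p = rep(p2p, length(z_mm)),
         station_z_mm = station_z, sac_z_mm = max(z_mm)),
    class = "spatiotemporal_flow")
}

# One imaged phantom subject ready for analyze_subject().
phantom_subject <- function(spec = phantom_spec(noise_sd = 0),
                            stations = csf_stations(),
                            id = "P01", group = "phantom", seed = NULL) {
  seg <- make_phantom_geometry(spec)
  flow <- lapply(stations$z_mm, function(z)
    make_pcmri_series(spec, z, seed = seed))
  names(flow) <- stations$station
  list(id = id, group = group, spec = spec, seg = seg, flow = flow)
}
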