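# Interpolation of flow along the spine and derived hydrodynamic
# parameters: Reynolds number, Womersley number, mean velocities, and
# pulse wave velocity from peak-systolic arrival times.

#' Interpolate station flow waveforms along the spine
#'
#' Builds the spatio-temporal flow field Q(z, t) on the geometry profile's
#' 1 mm axial grid and the stations' common time grid. At each time sample
#' the flow is linearly interpolated in z between stations; above the most
#' cranial station the flow is extended as constant, and below the most
#' caudal station it tapers linearly to an appended boundary node with
#' Q = 0 at the dural sac end (a closed sac admits no flow through its
#' terminus). Per-z peak systolic/diastolic flow and arrival times are
#' extracted on the grid.
#'
#' @param aw An `aligned_waveforms` set resampled with
#'   [resample_aligned()] (each station waveform carries its `z_mm`), or a
#'   plain named list of [flow_waveform()]s on one common time grid.
#' @param geometry A [geometry_profile()] supplying the axial grid and the
#'   dural sac position.
#' @return An object of class `spatiotemporal_flow`: `z_mm`, `z_norm`,
#'   `times`, `Q` (length(z) x length(t) matrix), `q_sys`, `t_sys`,
#'   `q_dia`, `t_dia`, `p2p`, `station_z_mm`, `sac_z_mm`.
#' @export
interpolate_flow_along_spine <- function(aw, geometry) {
  stopifnot(inherits(geometry, "geometry_profile"))
  wfs <- if (inherits(aw, "aligned_waveforms")) {
    if (is.null(aw$resampled))
      stop("resample the aligned set first (resample_aligned)")
    aw$resampled
  } else aw
  stopifnot(length(wfs) >= 2)
  zs <- vapply(wfs, `[[`, 0, "z_mm")
  if (anyNA(zs)) stop("every waveform needs a station position z_mm")
  times <- wfs[[1]]$times
  for (w in wfs) stopifnot(length(w$times) == length(times))
  ord <- order(zs)
  zs <- zs[ord]
  Qs <- do.call(rbind, lapply(wfs[ord], `[[`, "q"))  # stations x time
  sac_z <- geometry$length_mm
  z <- geometry$slices$z_mm
  if (any(zs > sac_z)) stop("station beyond the dural sac end")

  # append the closed-sac boundary node Q = 0 (unless a station sits there)
  if (max(zs) < sac_z) {
    zs_fit <- c(zs, sac_z)
    Qs <- rbind(Qs, 0)
  } else zs_fit <- zs

  Q <- matrix(0, length(z), length(times))
  for (j in seq_along(times)) {
    Q[, j] <- approx(zs_fit, Qs[, j], xout = z, rule = 2)$y
  }

  i_sys <- apply(Q, 1, which.min)
  i_dia <- apply(Q, 1, which.max)
  q_sys <- Q[cbind(seq_along(z), i_sys)]
  q_dia <- Q[cbind(seq_along(z), i_dia)]

  structure(
    list(z_mm = z, z_norm = geometry$slices$z_norm, times = times, Q = Q,
         q_sys = q_sys, t_sys = times[i_sys],
         q_dia = q_dia, t_dia = times[i_dia],
         p2p = q_dia - q_sys,
         station_z_mm = zs, sac_z_mm = sac_z),
    class = "spatiotemporal_flow"
  )
}

#' @export
print.spatiotemporal_flow <- function(x, ...) {
  cat(sprintf(
    "Spatio-temporal flow: %d z x %d t | peak systolic %.3f cm^3/s at z = %.0f mm\n",
    length(x$z_mm), length(x$times), min(x$q_sys),
    x$z_mm[which.min(x$q_sys)]))
  invisible(x)
}

#' Reynolds number profile
#'
#' `Re(z) = |Q_sys(z)| D_H(z) / (nu A_cs(z))`, using the magnitude of the
#' peak systolic (most negative) flow. Flow with Re < 2300 is flagged
#' laminar.
#'
#' @param flow A `spatiotemporal_flow`.
#' @param geometry The matching [geometry_profile()].
#' @param nu Kinematic viscosity in cm^2/s; default
#'   [csf_kinematic_viscosity()].
#' @return data.frame `z_mm`, `re`, `laminar`.
#' @export
reynolds_profile <- function(flow, geometry, nu = csf_kinematic_viscosity()) {
  .check_same_grid(flow, geometry)
  a_cs <- geometry$slices$a_cs
  if (any(a_cs <= 0)) stop("zero SSS area in profile")
  re <- abs(flow$q_sys) * geometry$slices$d_h / (nu * a_cs)
  data.frame(z_mm = flow$z_mm, re = re, laminar = re < 2300)
}

#' Womersley number profile
#'
#' `alpha(z) = D_H(z) sqrt(omega / nu)`. Two conventions for the cardiac
#' pulsation frequency are provided: `"angular"` (default) with
#' `omega = 2 pi / T`, and `"literature"` with `omega = 2 / T` (a convention
#' that appears in parts of the CSF literature, likely a dropped factor of
#' pi; both are kept so either set of published values can be matched).
#'
#' @param geometry A [geometry_profile()].
#' @param period Cardiac cycle duration T in seconds.
#' @param nu Kinematic viscosity (cm^2/s).
#' @param convention `"angular"` or `"literature"`.
#' @return data.frame `z_mm`, `alpha`.
#' @export
womersley_profile <- function(geometry, period,
                              nu = csf_kinematic_viscosity(),
                              convention = c("angular", "literature")) {
  stopifnot(inherits(geometry, "geometry_profile"), period > 0, nu > 0)
  convention <- match.arg(convention)
  omega <- if (convention == "angular") 2 * pi / period else 2 / period
  data.frame(z_mm = geometry$slices$z_mm,
             alpha = geometry$slices$d_h * sqrt(omega / nu))
}

#' Mean velocity profiles
#'
#' Signed peak systolic and diastolic mean velocities,
#' `U(z) = Q(z) / A_cs(z)`.
#'
#' @inheritParams reynolds_profile
#' @return data.frame `z_mm`, `u_sys`, `u_dia`.
#' @export
velocity_profiles <- function(flow, geometry) {
  .check_same_grid(flow, geometry)
  a_cs <- geometry$slices$a_cs
  if (any(a_cs <= 0)) stop("zero SSS area in profile")
  data.frame(z_mm = flow$z_mm,
             u_sys = flow$q_sys / a_cs,
             u_dia = flow$q_dia / a_cs)
}

.check_same_grid <- function(flow, geometry) {
  stopifnot(inherits(flow, "spatiotemporal_flow"),
            inherits(geometry, "geometry_profile"),
            length(flow$z_mm) == nrow(geometry$slices),
            max(abs(flow$z_mm - geometry$slices$z_mm)) < 1e-9)
}

#' Pulse wave velocity from peak-systolic arrival times
#'
#' Ordinary least squares of the arrival time of the peak systolic flow on
#' axial position: `t_sys(z) = intercept + slope * z`; PWV = 1 / slope
#' (cm/s). Arrival time is the measured, quantized quantity, so it is
#' regressed on z by default; `fit = "z_on_t"` exposes the transposed
#' regression.
#'
#' The fit uses only z where the local peak-to-peak flow exceeds
#' `pulsation_threshold`, and by default only the axial span actually
#' covered by measurement stations (`span = "stations"`): below the most
#' caudal station the interpolant is a pure amplitude taper whose arrival
#' time is constant and would bias the slope.
#'
#' Identical arrival times everywhere give a zero slope, reported as an
#' infinite-PWV flag; negative or unstable slopes are reported as-is with
#' diagnostics, never clipped.
#'
#' @param flow A `spatiotemporal_flow`.
#' @param pulsation_threshold Minimum local peak-to-peak flow (cm^3/s).
#' @param span `"stations"` (default) or `"all"`.
#' @param fit `"t_on_z"` (default) or `"z_on_t"`.
#' @return A list of class `pwv_fit`: `pwv_cm_s`, `slope_s_per_cm`,
#'   `intercept_s`, `r_squared`, `n`, `infinite`.
#' @export
pulse_wave_velocity <- function(flow, pulsation_threshold = 0.1,
                                span = c("stations", "all"),
                                fit = c("t_on_z", "z_on_t")) {
  stopifnot(inherits(flow, "spatiotemporal_flow"))
  span <- match.arg(span)
  fit <- match.arg(fit)
  use <- flow$p2p > pulsation_threshold
  if (span == "stations")
    use <- use & flow$z_mm >= min(flow$station_z_mm) &
      flow$z_mm <= max(flow$station_z_mm)
  if (sum(use) < 3)
    stop("fewer than 3 axial positions with pulsatile flow")
  z_cm <- mm_to_cm(flow$z_mm[use])
  t_sys <- flow$t_sys[use]

  if (diff(range(t_sys)) < 1e-12) {
    return(structure(list(pwv_cm_s = Inf, slope_s_per_cm = 0,
                          intercept_s = t_sys[1], r_squared = NA_real_,
                          n = sum(use), infinite = TRUE),
                     class = "pwv_fit"))
  }
  if (fit == "t_on_z") {
    m <- lm(t_sys ~ z_cm)
    slope <- unname(coef(m)[2])
    pwv <- 1 / slope
    ss_tot <- sum((t_sys - mean(t_sys))^2)
  } else {
    m <- lm(z_cm ~ t_sys)
    pwv <- unname(coef(m)[2])
    slope <- 1 / pwv
    ss_tot <- sum((z_cm - mean(z_cm))^2)
  }
  structure(
    list(pwv_cm_s = pwv, slope_s_per_cm = slope,
         intercept_s = unname(coef(m)[1]),
         r_squared = 1 - sum(stats::residuals(m)^2) / ss_tot,
         n = sum(use), infinite = FALSE),
    class = "pwv_fit"
  )
}

#' @export
print.pwv_fit <- function(x, ...) {
  if (x$infinite) {
    cat("PWV: infinite (identical arrival times at all", x$n, "positions)\n")
  } else {
    cat(sprintf("PWV: %.1f cm/s (slope %.3g s/cm, R^2 %.3f, n = %d)\n",
                x$pwv_cm_s, x$slope_s_per_cm, x$r_squared, x$n))
  }
  invisible(x)
}
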