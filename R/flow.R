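# Conversion of phase/velocity images to volumetric flow waveforms and
# extraction of per-station feature points.

#' Volumetric flow waveform at one station
#'
#' One cardiac cycle of volumetric CSF flow at a single axial station.
#' Flow is signed with caudal flow negative (see [caudal_sign()]).
#'
#' @param times Sample times in seconds, length `n_phases`, in `[0, T)`.
#' @param q Flow samples in cm^3/s.
#' @param period Cardiac cycle duration T in seconds.
#' @param station Station label (e.g. `"C2-C3"`) or `NA`.
#' @param z_mm Axial position of the station (mm below FM) or `NA`.
#' @param a_cs SSS cross-sectional area at the station (cm^2) or `NA`.
#' @return An object of class `flow_waveform`.
#' @export
flow_waveform <- function(times, q, period, station = NA_character_,
                          z_mm = NA_real_, a_cs = NA_real_) {
  stopifnot(length(times) == length(q), length(times) >= 2,
            period > 0, !is.unsorted(times))
  structure(
    list(times = as.numeric(times), q = as.numeric(q),
         period = as.numeric(period), station = station,
         z_mm = z_mm, a_cs = a_cs),
    class = "flow_waveform"
  )
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "Flow waveform%s: %d phases over T = %.3f s, range [%.3f, %.3f] cm^3/s\n",
    if (is.na(x$station)) "" else paste0(" at ", x$station),
    length(x$q), x$period, min(x$q), max(x$q)))
  invisible(x)
}

#' Convert phase images to velocity
#'
#' Standard phase-contrast relation: a phase of +/- pi maps to +/- VENC,
#' i.e. `v = venc * phase / pi`.
#'
#' @param phase Phase values in radians, in `[-pi, pi]`.
#' @param venc Velocity-encoding limit in cm/s.
#' @return Velocities in cm/s.
#' @export
phase_to_velocity <- function(phase, venc) {
  stopifnot(venc > 0)
  if (any(abs(phase) > pi + 1e-9, na.rm = TRUE))
    stop("phase outside [-pi, pi]; input may be unscaled")
  venc * phase / pi
}

#' Integrate a velocity series over an ROI into a flow waveform
#'
#' Volumetric flow as the voxel-area-weighted sum of velocities inside the
#' region of interest at each cardiac phase: `Q(t) = A_voxel * sum v(t)`.
#' The ROI area is recorded as `A_voxel * |mask|`.
#'
#' @param series Either a `pcmri_series` (from [make_pcmri_series()]), in
#'   which case the remaining arguments default to its fields, or a plain
#'   `n_phases x nx x ny` velocity array (cm/s).
#' @param mask Logical in-plane ROI; must be nonempty.
#' @param voxel_area_cm2 In-plane area of one voxel (cm^2).
#' @param times,period Sample times and cycle duration (seconds).
#' @param station,z_mm Optional station metadata.
#' @return A [flow_waveform()] with `a_cs` set to the ROI area.
#' @export
integrate_flow <- function(series, mask = NULL, voxel_area_cm2 = NULL,
                           times = NULL, period = NULL,
                           station = NA_character_, z_mm = NA_real_) {
  if (inherits(series, "pcmri_series")) {
    if (is.null(mask)) mask <- series$mask
    if (is.null(voxel_area_cm2)) voxel_area_cm2 <- series$voxel_area_cm2
    if (is.null(times)) times <- series$times
    if (is.null(period)) period <- series$period
    if (is.na(z_mm)) z_mm <- series$station_z_mm
    series <- series$v
  }
  stopifnot(is.array(series), length(dim(series)) == 3,
            is.logical(mask), any(mask),
            dim(series)[2] == nrow(mask), dim(series)[3] == ncol(mask),
            voxel_area_cm2 > 0, dim(series)[1] >= 8)
  q <- vapply(seq_len(dim(series)[1]),
              function(i) voxel_area_cm2 * sum(series[i, , ][mask]), 0)
  flow_waveform(times = times, q = q, period = period, station = station,
                z_mm = z_mm, a_cs = voxel_area_cm2 * sum(mask))
}

#' Offset-correct a flow waveform to zero net flow
#'
#' Subtracts the time-mean so the net flow over the cycle is exactly
#' 0 cm^3/s. Idempotent.
#'
#' @param w A [flow_waveform()].
#' @return The offset-corrected waveform.
#' @export
offset_correct <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  w$q <- w$q - mean(w$q)
  w
}

#' Peak systolic and diastolic feature points
#'
#' The feature points of an offset-corrected waveform: the systolic peak is
#' the most negative sample (caudal flow is negative), the diastolic peak
#' the most positive. Velocities are obtained by dividing flow by the SSS
#' cross-sectional area at the station. A waveform whose peak-to-peak
#' amplitude falls below `pulsation_threshold` is flagged `no_pulsation`
#' (near-zero flow; such stations/subjects are excluded from hydrodynamic
#' analyses upstream).
#'
#' @param w A [flow_waveform()] (offset-corrected).
#' @param a_cs SSS area (cm^2) used for the velocity features; defaults to
#'   `w$a_cs`.
#' @param pulsation_threshold Peak-to-peak flow (cm^3/s) below which the
#'   waveform counts as non-pulsatile. Default 0.1.
#' @return A list of class `feature_points`: `q_sys`, `t_sys`, `q_dia`,
#'   `t_dia`, `u_sys`, `u_dia`, `no_pulsation`.
#' @export
feature_points <- function(w, a_cs = w$a_cs, pulsation_threshold = 0.1) {
  stopifnot(inherits(w, "flow_waveform"))
  p2p <- diff(range(w$q))
  if (p2p < pulsation_threshold) {
    return(structure(list(q_sys = NA_real_, t_sys = NA_real_,
                          q_dia = NA_real_, t_dia = NA_real_,
                          u_sys = NA_real_, u_dia = NA_real_,
                          no_pulsation = TRUE),
                     class = "feature_points"))
  }
  i_sys <- which.min(w$q)
  i_dia <- which.max(w$q)
  q_sys <- w$q[i_sys]
  q_dia <- w$q[i_dia]
  structure(
    list(q_sys = q_sys, t_sys = w$times[i_sys],
         q_dia = q_dia, t_dia = w$times[i_dia],
         u_sys = if (is.na(a_cs)) NA_real_ else q_sys / a_cs,
         u_dia = if (is.na(a_cs)) NA_real_ else q_dia / a_cs,
         no_pulsation = FALSE),
    class = "feature_points"
  )
}
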