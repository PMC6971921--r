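# Synthetic phantom and cohort generator.
#
# The phantom is a straight-axis spinal canal: concentric elliptical cord
# and dura cross-sections whose (geometric-mean) radii are monotone-cubic
# interpolations of control points along z. Through-plane velocity series
# emulate retrospectively gated PCMRI: a prescribed pulsatile waveform
# propagates caudally at a fixed wave speed with exponential amplitude
# decay, is spread uniformly over the annulus (plug profile), and is
# corrupted by Gaussian velocity noise and, optionally, VENC phase wrap.
#
# Default geometry and waveform constants were calibrated once, at design
# time, so that the analytic spine-averaged values of the default phantom
# match reported healthy-adult values (SSS cross-section ~1.78 cm^2, wetted
# perimeter ~7.53 cm, cord area 0.35 cm^2, dura area 2.13 cm^2, SSS volume
# ~107 cm^3); see the methods vignette.

.default_cord_knots <- cbind(
  z_mm = c(0, 30, 90, 150, 250, 330, 420, 470, 510, 545, 600),
  r_cm = c(0.3862, 0.4066, 0.4371, 0.3659, 0.3252, 0.3252, 0.3862,
           0.3049, 0.1830, 0.1016, 0.0711)
)

.default_dura_knots <- cbind(
  z_mm = c(0, 30, 90, 150, 250, 330, 420, 480, 540, 600),
  r_cm = c(1.0908, 0.9869, 0.9350, 0.8311, 0.7791, 0.8103, 0.9142,
           0.8519, 0.5714, 0.3117)
)

#' Specification of a pulsatile flow waveform
#'
#' A zero-mean cardiac-periodic volumetric flow waveform expressed as a sum
#' of sinusoidal harmonics: `Q(t) = sum_k a_k sin(2 pi k t / T + phi_k)`.
#' There is no DC term, so the waveform has zero mean by construction (net
#' flow over one cycle is zero). The default shape has a sharp caudal
#' (negative) systolic peak of 4.23 cm^3/s at ~0.16 T followed by a broader
#' cranial diastolic phase, with a cycle duration of 956 ms.
#'
#' @param period Cardiac cycle duration T in seconds.
#' @param harmonic_amplitudes Amplitudes a_k (cm^3/s) for harmonics 1..K.
#' @param harmonic_phases Phases phi_k in radians, same length.
#' @param systolic_peak_sign Sign of the systolic peak; `-1` means the
#'   systolic (caudal) peak is the waveform minimum.
#' @return An object of class `waveform_spec`.
#' @seealso [synthesize_waveform()]
#' @export
waveform_spec <- function(period = 0.956,
                          harmonic_amplitudes = c(2.7053, 1.2174, 0.4058),
                          harmonic_phases = c(3.9270, 2.6208, 1.3046),
                          systolic_peak_sign = -1) {
  stopifnot(is.numeric(period), length(period) == 1, period > 0,
            length(harmonic_amplitudes) == length(harmonic_phases),
            all(harmonic_amplitudes >= 0),
            systolic_peak_sign %in% c(-1, 1))
  structure(
    list(period = period,
         harmonic_amplitudes = as.numeric(harmonic_amplitudes),
         harmonic_phases = as.numeric(harmonic_phases),
         systolic_peak_sign = systolic_peak_sign),
    class = "waveform_spec"
  )
}

# Continuous evaluation of the prescribed waveform at arbitrary times.
.eval_waveform <- function(spec, t) {
  q <- numeric(length(t))
  for (k in seq_along(spec$harmonic_amplitudes)) {
    q <- q + spec$harmonic_amplitudes[k] *
      sin(2 * pi * k * t / spec$period + spec$harmonic_phases[k])
  }
  q
}

#' Sample a prescribed waveform over one cardiac cycle
#'
#' Evaluates the harmonic series at `n_phases` uniform sample times over one
#' period, mimicking a retrospectively gated acquisition binned into
#' `n_phases` cardiac phases. The sampled waveform has exactly zero mean
#' (harmonics of order < `n_phases` sum to zero on a uniform grid; any
#' residual rounding is removed explicitly).
#'
#' @param spec A [waveform_spec()].
#' @param n_phases Number of cardiac phases (>= 8; acquisitions typically
#'   use 30).
#' @return A [flow_waveform()] with `times = (0:(n-1)) * T / n`.
#' @export
synthesize_waveform <- function(spec, n_phases = 30) {
  stopifnot(inherits(spec, "waveform_spec"),
            n_phases >= 8, n_phases == round(n_phases))
  times <- (seq_len(n_phases) - 1) * spec$period / n_phases
  q <- .eval_waveform(spec, times)
  q <- q - mean(q)
  flow_waveform(times = times, q = q, period = spec$period)
}

#' Specification of a synthetic spinal-canal phantom
#'
#' Describes a straight-axis phantom of the spinal subarachnoid space:
#' concentric cord and dura cross-sections with monotone-cubic interpolated
#' radii, a prescribed pulsatile waveform propagating caudally at
#' `pwv_true`, exponential amplitude decay along z, Gaussian velocity
#' noise, and a velocity-encoding limit (VENC).
#'
#' Cross-sections are ellipses of fixed aspect ratio; `r` in the knot
#' tables is the geometric-mean semi-axis, so the cross-sectional area is
#' `pi r^2` independent of aspect. The dura defaults to aspect 1.982
#' (laterally elongated), which reproduces realistic wetted perimeters that
#' circular sections cannot.
#'
#' @param length_mm Axial length from foramen magnum to dural sac end (mm).
#' @param cord_radius_knots,dura_radius_knots Two-column matrices
#'   `(z_mm, r_cm)` of radius control points. Dura radius must exceed cord
#'   radius everywhere (after interpolation).
#' @param cord_aspect,dura_aspect Ellipse aspect ratios (major/minor axis).
#' @param voxel_size_mm Voxel spacing `(dx, dy, dz)` of the segmentation
#'   grid in mm.
#' @param flow_voxel_mm In-plane (isotropic) voxel size of velocity images
#'   in mm; default 0.781 mm as in typical spinal PCMRI.
#' @param waveform A [waveform_spec()].
#' @param pwv_true Prescribed pulse wave velocity in cm/s.
#' @param amplitude_decay Per-mm multiplicative amplitude decay factor in
#'   (0, 1]; the flow amplitude at depth z mm is scaled by
#'   `amplitude_decay^z`. The default 0.99699 corresponds to a decay to 25%
#'   at the L3--L4 level (460 mm).
#' @param noise_sd SD of additive Gaussian velocity noise (cm/s).
#' @param venc Velocity-encoding limit (cm/s); default 10.
#' @param seed Integer seed used when this spec is realized.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(length_mm = 600,
                         cord_radius_knots = .default_cord_knots,
                         dura_radius_knots = .default_dura_knots,
                         cord_aspect = 1.0,
                         dura_aspect = 1.982,
                         voxel_size_mm = c(0.437, 0.437, 1.0),
                         flow_voxel_mm = 0.781,
                         waveform = waveform_spec(),
                         pwv_true = 347.41,
                         amplitude_decay = 0.996990,
                         noise_sd = 0.3,
                         venc = 10,
                         seed = 1L) {
  stopifnot(length_mm > 0, pwv_true > 0,
            amplitude_decay > 0, amplitude_decay <= 1,
            noise_sd >= 0, venc > 0,
            cord_aspect >= 1, dura_aspect >= 1,
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0),
            inherits(waveform, "waveform_spec"))
  cord_radius_knots <- .as_knots(cord_radius_knots)
  dura_radius_knots <- .as_knots(dura_radius_knots)
  spec <- structure(
    list(length_mm = length_mm,
         cord_radius_knots = cord_radius_knots,
         dura_radius_knots = dura_radius_knots,
         cord_aspect = cord_aspect,
         dura_aspect = dura_aspect,
         voxel_size_mm = as.numeric(voxel_size_mm),
         flow_voxel_mm = flow_voxel_mm,
         waveform = waveform,
         pwv_true = pwv_true,
         amplitude_decay = amplitude_decay,
         noise_sd = noise_sd,
         venc = venc,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  # reject geometries where the dura does not clear the cord anywhere along z
  zg <- seq(0, length_mm, by = 1)
  rc <- phantom_radius(spec, zg, "cord")
  rd <- phantom_radius(spec, zg, "dura")
  if (any(rc <= 0) || any(rd <= 0))
    stop("interpolated radii must be positive everywhere")
  # compare the cord's major semi-axis to the dura's minor semi-axis so that
  # the full ellipse, not just the mean radius, stays inside the dura
  if (any(rd / sqrt(spec$dura_aspect) <= rc * sqrt(spec$cord_aspect)))
    stop("dura radius must exceed cord radius at every axial position")
  spec
}

.as_knots <- function(k) {
  k <- as.matrix(k)
  stopifnot(ncol(k) == 2, nrow(k) >= 2, all(k[, 2] > 0),
            !is.unsorted(k[, 1], strictly = TRUE))
  colnames(k) <- c("z_mm", "r_cm")
  k
}

#' Interpolated phantom radius at axial positions
#'
#' Monotone cubic (Fritsch-Carlson) interpolation of the radius control
#' points, clamped to the end values outside the knot range.
#'
#' @param spec A [phantom_spec()].
#' @param z_mm Axial positions in mm.
#' @param which `"cord"` or `"dura"`.
#' @return Radii in cm (geometric-mean semi-axis).
#' @export
phantom_radius <- function(spec, z_mm, which = c("cord", "dura")) {
  which <- match.arg(which)
  k <- if (which == "cord") spec$cord_radius_knots else spec$dura_radius_knots
  f <- splinefun(k[, 1], k[, 2], method = "monoH.FC")
  z <- pmin(pmax(z_mm, min(k[, 1])), max(k[, 1]))
  f(z)
}

# Ramanujan's second approximation to the ellipse perimeter (relative error
# < 1e-6 at the aspect ratios used here). r is the geometric-mean semi-axis.
.ellipse_perimeter <- function(r, aspect) {
  a <- r * sqrt(aspect)
  b <- r / sqrt(aspect)
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Analytic slice geometry of a phantom
#'
#' Closed-form per-slice areas, perimeters and hydraulic diameter of the
#' phantom at the requested axial positions. Serves as ground truth for the
#' voxelized geometry pipeline.
#'
#' @inheritParams phantom_radius
#' @return A data.frame with the same columns as a [geometry_profile()]
#'   slice table (`z_mm`, `a_c`, `a_d`, `a_cs`, `p_c`, `p_d`, `p_cs`,
#'   `d_h`).
#' @export
phantom_analytic_geometry <- function(spec, z_mm) {
  rc <- phantom_radius(spec, z_mm, "cord")
  rd <- phantom_radius(spec, z_mm, "dura")
  a_c <- pi * rc^2
  a_d <- pi * rd^2
  p_c <- .ellipse_perimeter(rc, spec$cord_aspect)
  p_d <- .ellipse_perimeter(rd, spec$dura_aspect)
  data.frame(z_mm = z_mm, a_c = a_c, a_d = a_d, a_cs = a_d - a_c,
             p_c = p_c, p_d = p_d, p_cs = p_c + p_d,
             d_h = 4 * (a_d - a_c) / (p_c + p_d))
}

#' Voxelize a phantom into a labelled segmentation volume
#'
#' Rasterizes the phantom onto a regular grid: at each axial layer, voxels
#' whose centre falls inside the cord ellipse are labelled cord (1), voxels
#' inside the dura ellipse but outside the cord are labelled CSF (2), and
#' the rest background (0).
#'
#' @param spec A [phantom_spec()].
#' @return A [segmentation_volume()].
#' @export
make_phantom_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size_mm
  zg <- seq(0, spec$length_mm, by = vs[3])
  rc <- phantom_radius(spec, zg, "cord")
  rd <- phantom_radius(spec, zg, "dura")
  half_cm <- max(rd) * sqrt(spec$dura_aspect) + 0.2  # 2 mm margin
  xs <- .centered_axis(half_cm, mm_to_cm(vs[1]))
  ys <- .centered_axis(half_cm, mm_to_cm(vs[2]))
  X2 <- outer(xs^2, rep(1, length(ys)))
  Y2 <- outer(rep(1, length(xs)), ys^2)
  labels <- array(0L, dim = c(length(xs), length(ys), length(zg)))
  ec <- spec$cord_aspect
  ed <- spec$dura_aspect
  for (k in seq_along(zg)) {
    # the 1e-9 slack keeps voxel centres that sit exactly on the boundary
    # inside, independent of last-bit interpolation noise
    in_cord <- X2 / (ec * rc[k]^2) + Y2 * ec / rc[k]^2 <= 1 + 1e-9
    in_dura <- X2 / (ed * rd[k]^2) + Y2 * ed / rd[k]^2 <= 1 + 1e-9
    sl <- matrix(0L, length(xs), length(ys))
    sl[in_dura] <- 2L
    sl[in_cord] <- 1L
    labels[, , k] <- sl
  }
  segmentation_volume(labels, spacing_mm = vs,
                      fm_index = 1L, sac_index = length(zg))
}

.centered_axis <- function(half_extent, step) {
  n <- ceiling(half_extent / step)
  seq(-n, n) * step
}

#' Simulate a gated through-plane velocity series at one station
#'
#' Generates an `n_phases x nx x ny` array of through-plane velocities
#' (cm/s) at axial position `station_z_mm`, on its own in-plane grid of
#' `flow_voxel_mm` spacing. Within the SSS annulus the velocity is the
#' delayed, decayed waveform divided by the local analytic SSS area (plug
#' profile): `v(t) = Q(t - z / pwv) * decay(z) / A_cs(z)`. Gaussian noise
#' of SD `noise_sd` is added everywhere (inside and outside the dura).
#' With `venc_wrap = TRUE`, velocities are wrapped into `[-venc, venc)` as
#' phase aliasing would: `v -> ((v + venc) mod 2 venc) - venc`.
#'
#' @param spec A [phantom_spec()].
#' @param station_z_mm Axial position of the imaging slice (mm below FM).
#' @param n_phases Number of cardiac phases.
#' @param profile Velocity profile across the annulus: `"plug"` (uniform,
#'   default) or `"poiseuille"` (annular Poiseuille shape scaled to the
#'   same flow).
#' @param venc_wrap Apply VENC wrap-around? Default `FALSE`.
#' @param seed Optional seed for the noise; when `NULL` the current RNG
#'   stream is used (as when called inside [make_cohort()]).
#' @return An object of class `pcmri_series`: list with elements `v`
#'   (array), `mask` (logical CSF matrix), `voxel_area_cm2`, `times`,
#'   `period`, `station_z_mm`, `venc`, and `q_true` (the noise-free
#'   delayed flow waveform, for validation).
#' @export
make_pcmri_series <- function(spec, station_z_mm, n_phases = 30,
                              profile = c("plug", "poiseuille"),
                              venc_wrap = FALSE, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  profile <- match.arg(profile)
  if (station_z_mm < 0 || station_z_mm > spec$length_mm)
    stop("station position lies outside the phantom")
  if (!is.null(seed))
    return(withr::with_seed(seed,
      make_pcmri_series(spec, station_z_mm, n_phases, profile, venc_wrap)))

  rc <- phantom_radius(spec, station_z_mm, "cord")
  rd <- phantom_radius(spec, station_z_mm, "dura")
  a_cs <- pi * (rd^2 - rc^2)
  h_cm <- mm_to_cm(spec$flow_voxel_mm)
  half_cm <- rd * sqrt(spec$dura_aspect) + 0.2
  xs <- .centered_axis(half_cm, h_cm)
  ys <- xs
  X2 <- outer(xs^2, rep(1, length(ys)))
  Y2 <- outer(rep(1, length(xs)), ys^2)
  ec <- spec$cord_aspect
  ed <- spec$dura_aspect
  in_cord <- X2 / (ec * rc^2) + Y2 * ec / rc^2 <= 1 + 1e-9
  in_dura <- X2 / (ed * rd^2) + Y2 * ed / rd^2 <= 1 + 1e-9
  mask <- in_dura & !in_cord

  period <- spec$waveform$period
  times <- (seq_len(n_phases) - 1) * period / n_phases
  tau <- mm_to_cm(station_z_mm) / spec$pwv_true           # seconds
  decay <- spec$amplitude_decay^station_z_mm
  q_true <- .eval_waveform(spec$waveform, times - tau) * decay

  shape <- matrix(0, length(xs), length(ys))
  if (profile == "plug") {
    shape[mask] <- 1
  } else {
    # annular Poiseuille: v(rho) ~ 1 - rho^2 + (1 - kappa^2) ln(rho) / ln(1/kappa)
    # evaluated on the elliptically stretched radius, then renormalized so the
    # masked mean is 1 (same integrated flow as plug).
    rho <- sqrt(X2 / ed + Y2 * ed) / rd
    kappa <- rc / rd
    prof <- 1 - rho^2 + (1 - kappa^2) * log(pmax(rho, 1e-9)) / log(1 / kappa)
    shape[mask] <- prof[mask] / mean(prof[mask])
  }

  v <- array(0, dim = c(n_phases, length(xs), length(ys)))
  for (i in seq_len(n_phases)) {
    vi <- shape * (q_true[i] / a_cs)
    if (spec$noise_sd > 0)
      vi <- vi + matrix(rnorm(length(vi), sd = spec$noise_sd),
                        nrow(vi), ncol(vi))
    if (venc_wrap)
      vi <- venc_wrap_velocity(vi, spec$venc)
    v[i, , ] <- vi
  }

  structure(
    list(v = v, mask = mask, voxel_area_cm2 = h_cm^2, times = times,
         period = period, station_z_mm = station_z_mm, venc = spec$venc,
         q_true = q_true),
    class = "pcmri_series"
  )
}

#' Wrap velocities beyond the VENC limit
#'
#' Velocities exceeding the encoding limit alias as the underlying phase
#' wraps: `v -> ((v + venc) mod 2 venc) - venc`. A prescribed velocity of
#' 12 cm/s at VENC 10 therefore appears at -8 cm/s.
#'
#' @param v Velocities in cm/s.
#' @param venc Velocity-encoding limit in cm/s.
#' @return Wrapped velocities in `[-venc, venc)`.
#' @export
venc_wrap_velocity <- function(v, venc) {
  ((v + venc) %% (2 * venc)) - venc
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `n_per_group` subjects per group from the base phantom with
#' per-subject lognormal-free normal jitter of radii, waveform amplitude,
#' cycle duration, and pulse wave velocity, after applying per-group
#' modifiers. The jitter magnitudes are fixed design constants of the
#' generator (radius scale SD 6%, amplitude scale SD 12%, PWV scale SD 15%,
#' cycle duration 956 +/- 138 ms truncated to \[600, 1264\] ms).
#'
#' Recognized per-group modifiers (entries of `group_params[[g]]`):
#' `amplitude_scale`, `pwv` (replaces the base value), `dura_radius_scale`,
#' `cord_radius_scale`, `period`, `noise_sd`.
#'
#' @param n_per_group Integer (scalar or one per group).
#' @param group_params Named list of per-group modifier lists; names are
#'   the group labels.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param base_spec Base [phantom_spec()] shared by all groups.
#' @param stations Station table (`station`, `z_mm`) to image; default
#'   [csf_stations()].
#' @param imaging If `TRUE` (default) each subject carries a voxelized
#'   segmentation and per-station velocity series; if `FALSE` only specs
#'   and ground truth (fast, for statistical calibration studies).
#' @param n_phases Cardiac phases per velocity series.
#' @param jitter Named list overriding the per-subject jitter SDs
#'   (`radius`, `amplitude`, `pwv`, `period`); zeroing them makes all
#'   subjects of a group identical.
#' @return A list of class `csf_cohort`: `subjects` (list), `groups`,
#'   `stations`, `seed`. Each subject holds `id`, `group`, `spec`,
#'   `truth` (pwv, amplitude and radius scales), and, with imaging, `seg`
#'   plus `flow` (named list of `pcmri_series`).
#' @export
make_cohort <- function(n_per_group, group_params, seed = 1L,
                        base_spec = phantom_spec(),
                        stations = csf_stations(),
                        imaging = TRUE, n_phases = 30,
                        jitter = list()) {
  stopifnot(length(group_params) >= 1, !is.null(names(group_params)),
            all(n_per_group >= 1))
  groups <- names(group_params)
  n_per_group <- rep_len(as.integer(n_per_group), length(groups))
  jit <- modifyList(.jitter_sd, jitter)

  withr::with_seed(as.integer(seed), {
    subjects <- list()
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      mod <- group_params[[g]]
      for (si in seq_len(n_per_group[gi])) {
        subjects[[length(subjects) + 1L]] <-
          .draw_subject(sprintf("%s%02d", toupper(substr(g, 1, 1)), si),
                        g, mod, base_spec, stations, imaging, n_phases,
                        jit)
      }
    }
    structure(list(subjects = subjects, groups = groups,
                   stations = stations, seed = as.integer(seed)),
              class = "csf_cohort")
  })
}

# generator jitter SDs (design constants; see methods vignette)
.jitter_sd <- list(radius = 0.06, amplitude = 0.12, pwv = 0.15,
                   period = 0.138)
.period_range <- c(0.600, 1.264)

.draw_subject <- function(id, group, mod, base, stations, imaging,
                          n_phases, jit = .jitter_sd) {
  r_scale <- rnorm(1, 1, jit$radius)
  a_scale <- rnorm(1, 1, jit$amplitude)
  p_scale <- rnorm(1, 1, jit$pwv)
  period <- min(max(rnorm(1, 0.956, jit$period), .period_range[1]),
                .period_range[2])
  r_scale <- max(r_scale, 0.5)
  a_scale <- max(a_scale, 0.1)
  p_scale <- max(p_scale, 0.3)

  amp_mod <- if (is.null(mod$amplitude_scale)) 1 else mod$amplitude_scale
  dura_mod <- if (is.null(mod$dura_radius_scale)) 1 else mod$dura_radius_scale
  cord_mod <- if (is.null(mod$cord_radius_scale)) 1 else mod$cord_radius_scale
  pwv_base <- if (is.null(mod$pwv)) base$pwv_true else mod$pwv
  if (!is.null(mod$period)) period <- mod$period
  noise_sd <- if (is.null(mod$noise_sd)) base$noise_sd else mod$noise_sd

  wf <- base$waveform
  wf$period <- period
  wf$harmonic_amplitudes <- wf$harmonic_amplitudes * amp_mod * a_scale

  ck <- base$cord_radius_knots
  dk <- base$dura_radius_knots
  ck[, 2] <- ck[, 2] * r_scale * cord_mod
  dk[, 2] <- dk[, 2] * r_scale * dura_mod

  spec <- phantom_spec(
    length_mm = base$length_mm,
    cord_radius_knots = ck, dura_radius_knots = dk,
    cord_aspect = base$cord_aspect, dura_aspect = base$dura_aspect,
    voxel_size_mm = base$voxel_size_mm, flow_voxel_mm = base$flow_voxel_mm,
    waveform = wf, pwv_true = pwv_base * p_scale,
    amplitude_decay = base$amplitude_decay,
    noise_sd = noise_sd, venc = base$venc, seed = base$seed
  )

  subj <- list(id = id, group = group, spec = spec,
               truth = list(pwv = spec$pwv_true,
                            amplitude_scale = amp_mod * a_scale,
                            radius_scale = r_scale,
                            period = period))
  if (imaging) {
    subj$seg <- make_phantom_geometry(spec)
    subj$flow <- lapply(seq_len(nrow(stations)), function(i)
      make_pcmri_series(spec, stations$z_mm[i], n_phases = n_phases))
    names(subj$flow) <- stations$station
  }
  subj
}

#' @export
print.csf_cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat("Synthetic CSF cohort:",
      paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      sprintf("| %d stations | seed %d\n", nrow(x$stations), x$seed))
  invisible(x)
}
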