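# End-to-end orchestration: geometry -> flow -> waveform -> hydrodynamics
# -> cohort statistics, with per-subject quarantine and a structured log.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its default. Defaults
#' follow standard spinal PCMRI acquisition and analysis conventions:
#' 10 ms resampling over a 1280 ms window, harmonics 1-7, alignment at
#' C2-C3, pulsation threshold 0.1 cm^3/s, VENC 10 cm/s, significance at
#' 0.05. Round-trips losslessly through YAML ([write_config()],
#' [read_config()]).
#'
#' @param stations Station table (`station`, `z_mm`); default
#'   [csf_stations()].
#' @param nu Kinematic viscosity (cm^2/s).
#' @param omega_convention `"angular"` or `"literature"` (see
#'   [womersley_profile()]).
#' @param normalizer Waveform normalizer (see [normalize_by_c23()]).
#' @param pad Diastolic padding mode (see [extend_and_resample()]).
#' @param pulsation_threshold Near-zero-flow threshold (cm^3/s).
#' @param dt_s,window_s Resampling interval and window (seconds).
#' @param n_harmonics Harmonics reported (default 7).
#' @param alpha Significance level.
#' @param ref_station Alignment/normalization reference station.
#' @param pwv_span,pwv_fit Options of [pulse_wave_velocity()].
#' @param spacing_mm Geometry slice spacing (mm).
#' @param venc Velocity-encoding limit (cm/s).
#' @param seed Seed recorded with the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(stations = csf_stations(),
                            nu = csf_kinematic_viscosity(),
                            omega_convention = "angular",
                            normalizer = "mean_abs",
                            pad = "hold",
                            pulsation_threshold = 0.1,
                            dt_s = 0.01, window_s = 1.28,
                            n_harmonics = 7, alpha = 0.05,
                            ref_station = "C2-C3",
                            pwv_span = "stations", pwv_fit = "t_on_z",
                            spacing_mm = 1, venc = 10, seed = 1L) {
  cfg <- list(stations = as.data.frame(stations), nu = nu,
              omega_convention = omega_convention, normalizer = normalizer,
              pad = pad, pulsation_threshold = pulsation_threshold,
              dt_s = dt_s, window_s = window_s,
              n_harmonics = as.integer(n_harmonics), alpha = alpha,
              ref_station = ref_station, pwv_span = pwv_span,
              pwv_fit = pwv_fit, spacing_mm = spacing_mm, venc = venc,
              seed = as.integer(seed))
  stopifnot(cfg$dt_s > 0, cfg$window_s > cfg$dt_s, cfg$nu > 0,
            cfg$n_harmonics >= 1, cfg$alpha > 0, cfg$alpha < 1,
            all(c("station", "z_mm") %in% names(cfg$stations)))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Analyze one subject end to end
#'
#' Runs geometry profiling, per-station flow integration and offset
#' correction, the near-zero-flow exclusion check, alignment/resampling/
#' normalization, harmonic analysis, spinal flow interpolation, and the
#' hydrodynamic profiles, returning a [summarize_subject()] object. If
#' every station is non-pulsatile the subject keeps its geometric summary
#' and is excluded from flow/hydrodynamic fields with reason
#' `"near-zero flow"`.
#'
#' @param subject A subject as produced by [make_cohort()] (elements
#'   `id`, `group`, `seg`, `flow`).
#' @param config A [pipeline_config()].
#' @param details If `TRUE`, attach the intermediate objects
#'   (`geometry`, `waveforms`, `aligned`, `stf`, `hydro`) as an attribute.
#' @return A `subject_summary`.
#' @export
analyze_subject <- function(subject, config = pipeline_config(),
                            details = FALSE) {
  stopifnot(!is.null(subject$seg), !is.null(subject$flow))
  geometry <- geometry_profile(subject$seg, spacing_mm = config$spacing_mm)

  waveforms <- list()
  for (st in names(subject$flow)) {
    ser <- subject$flow[[st]]
    w <- integrate_flow(ser, station = st)
    w <- offset_correct(w)
    w$a_cs <- profile_value_at(geometry, w$z_mm, "a_cs")
    waveforms[[st]] <- w
  }

  p2p <- vapply(waveforms, function(w) diff(range(w$q)), 0)
  if (all(p2p < config$pulsation_threshold)) {
    return(summarize_subject(subject$id, subject$group, geometry,
                             exclusions = "near-zero flow"))
  }

  feats <- do.call(rbind, lapply(names(waveforms), function(st) {
    fp <- feature_points(waveforms[[st]],
                         pulsation_threshold = config$pulsation_threshold)
    data.frame(station = st, q_sys = fp$q_sys, t_sys = fp$t_sys,
               q_dia = fp$q_dia, t_dia = fp$t_dia,
               u_sys = fp$u_sys, u_dia = fp$u_dia)
  }))

  aligned <- align_by_steepest_descent(waveforms, ref = config$ref_station)
  aligned <- resample_aligned(aligned, window_s = config$window_s,
                              dt_s = config$dt_s, pad = config$pad)

  stf <- interpolate_flow_along_spine(aligned, geometry)
  hydro <- list(
    re = reynolds_profile(stf, geometry, nu = config$nu),
    alpha = womersley_profile(geometry, waveforms[[1]]$period,
                              nu = config$nu,
                              convention = config$omega_convention),
    vel = velocity_profiles(stf, geometry),
    flow = stf,
    pwv = pulse_wave_velocity(stf,
                              pulsation_threshold = config$pulsation_threshold,
                              span = config$pwv_span, fit = config$pwv_fit)
  )

  normalized <- normalize_by_c23(aligned, normalizer = config$normalizer)
  spectra <- do.call(rbind, lapply(names(normalized$resampled), function(st) {
    sp <- harmonic_spectrum(normalized$resampled[[st]],
                            n_harmonics = config$n_harmonics)
    cbind(station = st, sp)
  }))

  out <- summarize_subject(subject$id, subject$group, geometry,
                           hydro = hydro, features = feats,
                           spectra = spectra)
  if (details)
    attr(out, "details") <- list(geometry = geometry, waveforms = waveforms,
                                 aligned = normalized, stf = stf,
                                 hydro = hydro)
  out
}

#' Run the full cohort pipeline
#'
#' Analyzes every subject (quarantining per-subject failures with their
#' error message rather than aborting the run), compares the two groups,
#' and optionally writes the result tables to `output_dir`. Deterministic
#' given the cohort and configuration: the analysis itself draws no random
#' numbers.
#'
#' @param cohort A `csf_cohort` from [make_cohort()] (or any list with a
#'   `subjects` element of the same shape).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for CSV/JSON/Markdown outputs (see
#'   [write_comparison()]).
#' @return A list of class `pipeline_result`: `summaries`, `comparison`
#'   (`NULL` unless exactly two groups survive), `failed` (named list of
#'   error messages), `log` (character vector of events).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         output_dir = NULL) {
  subjects <- cohort$subjects
  summaries <- list()
  failed <- list()
  log <- c(sprintf("pipeline: %d subjects, normalizer=%s, pad=%s, omega=%s",
                   length(subjects), config$normalizer, config$pad,
                   config$omega_convention))
  for (s in subjects) {
    res <- tryCatch(analyze_subject(s, config), error = function(e) e)
    if (inherits(res, "error")) {
      failed[[s$id]] <- conditionMessage(res)
      log <- c(log, sprintf("subject %s: FAILED (%s)", s$id, failed[[s$id]]))
    } else {
      summaries[[length(summaries) + 1L]] <- res
      if (length(res$exclusions))
        log <- c(log, sprintf("subject %s: excluded from flow analyses (%s)",
                              s$id, paste(res$exclusions, collapse = "; ")))
    }
  }
  groups <- unique(vapply(summaries, `[[`, "", "group"))
  comparison <- if (length(groups) == 2)
    compare_groups(summaries, alpha = config$alpha) else NULL
  out <- structure(list(summaries = summaries, comparison = comparison,
                        failed = failed, log = log),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_comparison(out, output_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d subjects analyzed, %d failed\n",
              length(x$summaries), length(x$failed)))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
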