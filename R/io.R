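# File-format plumbing: NIfTI volumes for segmentations and velocity
# series, JSON sidecars for ground truth and configuration, CSV tables for
# profiles and comparisons. All floating-point CSV output uses 6
# significant digits; units are embedded in the column headers.

#' Write / read a segmentation volume as NIfTI
#'
#' Labels are stored as integers with the voxel spacing in the NIfTI
#' `pixdim`; FM and dural-sac layer indices travel in a JSON sidecar next
#' to the image (`<file>.json`).
#'
#' @param seg A [segmentation_volume()].
#' @param file Output path (`.nii` or `.nii.gz`).
#' @return `file`, invisibly.
#' @export
write_segmentation_nifti <- function(seg, file) {
  stopifnot(inherits(seg, "segmentation_volume"))
  img <- RNifti::asNifti(seg$labels, pixdim = seg$spacing_mm)
  RNifti::writeNifti(img, file)
  jsonlite::write_json(
    list(fm_index = seg$fm_index, sac_index = seg$sac_index,
         spacing_mm = seg$spacing_mm),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_segmentation_nifti
#' @export
read_segmentation_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  segmentation_volume(array(as.integer(img), dim = dim(img)),
                      spacing_mm = meta$spacing_mm,
                      fm_index = meta$fm_index, sac_index = meta$sac_index)
}

#' Write / read a velocity series as 4-D NIfTI
#'
#' Stored as `nx x ny x 1 x n_phases` floating point (cm/s), with mask,
#' timing, VENC and station position in a JSON sidecar.
#'
#' @param series A `pcmri_series`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_flow_series_nifti <- function(series, file) {
  stopifnot(inherits(series, "pcmri_series"))
  d <- dim(series$v)
  arr <- array(aperm(series$v, c(2, 3, 1)), dim = c(d[2], d[3], 1, d[1]))
  vox <- sqrt(series$voxel_area_cm2) * 10  # mm
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(vox, vox, 1, 1)), file)
  jsonlite::write_json(
    list(times_s = series$times, period_s = series$period,
         station_z_mm = series$station_z_mm, venc = series$venc,
         voxel_area_cm2 = series$voxel_area_cm2,
         mask = which(series$mask), mask_dim = dim(series$mask)),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_flow_series_nifti
#' @export
read_flow_series_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  d <- dim(img)
  mask <- matrix(FALSE, meta$mask_dim[1], meta$mask_dim[2])
  mask[meta$mask] <- TRUE
  structure(
    list(v = aperm(array(img, dim = c(d[1], d[2], d[4])), c(3, 1, 2)),
         mask = mask, voxel_area_cm2 = meta$voxel_area_cm2,
         times = meta$times_s, period = meta$period_s,
         station_z_mm = meta$station_z_mm, venc = meta$venc,
         q_true = NULL),
    class = "pcmri_series"
  )
}

#' Write a synthetic cohort to a directory tree
#'
#' One directory per subject containing `seg.nii.gz`,
#' `flow_<station>.nii.gz` and `meta.json` (group, ground truth, station
#' table).
#'
#' @param cohort A `csf_cohort` with imaging.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    write_segmentation_nifti(s$seg, file.path(sd, "seg.nii.gz"))
    for (st in names(s$flow)) {
      safe <- gsub("[^A-Za-z0-9]", "", st)
      write_flow_series_nifti(s$flow[[st]],
                              file.path(sd, sprintf("flow_%s.nii.gz", safe)))
    }
    jsonlite::write_json(
      list(id = s$id, group = s$group, truth = s$truth,
           stations = cohort$stations),
      file.path(sd, "meta.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `csf_cohort` (without the generator specs).
#' @export
read_cohort <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  subjects <- lapply(subs, function(sd) {
    meta <- jsonlite::read_json(file.path(sd, "meta.json"),
                                simplifyVector = TRUE)
    seg <- read_segmentation_nifti(file.path(sd, "seg.nii.gz"))
    stations <- as.data.frame(meta$stations)
    flow <- lapply(stations$station, function(st) {
      safe <- gsub("[^A-Za-z0-9]", "", st)
      read_flow_series_nifti(file.path(sd, sprintf("flow_%s.nii.gz", safe)))
    })
    names(flow) <- stations$station
    list(id = meta$id, group = meta$group, truth = meta$truth,
         seg = seg, flow = flow)
  })
  groups <- unique(vapply(subjects, `[[`, "", "group"))
  stations <- as.data.frame(jsonlite::read_json(
    file.path(subs[1], "meta.json"), simplifyVector = TRUE)$stations)
  structure(list(subjects = subjects, groups = groups,
                 stations = stations, seed = NA_integer_),
            class = "csf_cohort")
}

.fmt6 <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}

#' Write a geometry profile as CSV + JSON summary
#'
#' Slice table columns carry units (`z_mm`, `A_c_cm2`, ..., `D_H_cm`); the
#' JSON summary holds the integrated volumes and surface areas and the
#' spine-averaged means +/- SD.
#'
#' @param profile A [geometry_profile()].
#' @param stem Output path stem (writes `<stem>.csv` and `<stem>.json`).
#' @return `stem`, invisibly.
#' @export
write_geometry_profile <- function(profile, stem) {
  sl <- profile$slices
  out <- data.frame(z_mm = sl$z_mm, z_norm = sl$z_norm,
                    A_c_cm2 = sl$a_c, A_d_cm2 = sl$a_d, A_cs_cm2 = sl$a_cs,
                    P_c_cm = sl$p_c, P_d_cm = sl$p_d, P_cs_cm = sl$p_cs,
                    D_H_cm = sl$d_h, missing = sl$missing)
  write.csv(.fmt6(out), paste0(stem, ".csv"), row.names = FALSE)
  summ <- list(
    volumes_cm3 = list(cord = profile$v_c, dura = profile$v_d,
                       sss = profile$v_cs),
    surface_areas_cm2 = list(cord = profile$sa_c, dura = profile$sa_d,
                             sss = profile$sa_cs),
    spine_averages = lapply(
      c(a_c = "a_c", a_d = "a_d", a_cs = "a_cs", p_c = "p_c", p_d = "p_d",
        p_cs = "p_cs", d_h = "d_h"),
      function(col) list(mean = mean(sl[[col]], na.rm = TRUE),
                         sd = sd(sl[[col]], na.rm = TRUE))),
    length_mm = profile$length_mm)
  jsonlite::write_json(summ, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Write pipeline comparison outputs
#'
#' Emits `group_summary.csv` (parameter, per-group mean +/- SD, percent
#' difference), `feature_tests.csv`, `harmonic_tests.csv`,
#' `subject_summaries.csv`, `pipeline_log.txt` and a human-readable
#' `report.md` into `dir`.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subj <- do.call(rbind, lapply(result$summaries, function(s) {
    data.frame(id = s$id, group = s$group, t(s$scalars),
               excluded = paste(s$exclusions, collapse = "; "))
  }))
  write.csv(.fmt6(subj), file.path(dir, "subject_summaries.csv"),
            row.names = FALSE)
  writeLines(result$log, file.path(dir, "pipeline_log.txt"))
  cmp <- result$comparison
  if (is.null(cmp)) return(invisible(dir))
  write.csv(.fmt6(cmp$params), file.path(dir, "group_summary.csv"),
            row.names = FALSE)
  if (nrow(cmp$feature_tests))
    write.csv(.fmt6(cmp$feature_tests), file.path(dir, "feature_tests.csv"),
              row.names = FALSE)
  if (nrow(cmp$harmonic_tests))
    write.csv(.fmt6(cmp$harmonic_tests),
              file.path(dir, "harmonic_tests.csv"), row.names = FALSE)
  writeLines(.comparison_markdown(cmp), file.path(dir, "report.md"))
  invisible(dir)
}

.comparison_markdown <- function(cmp) {
  p <- cmp$params
  lines <- c(
    sprintf("# Group comparison: %s vs %s", cmp$groups["reference"],
            cmp$groups["comparison"]),
    "",
    sprintf("Reference group n = %d, comparison group n = %d.",
            cmp$n[[cmp$groups["reference"]]],
            cmp$n[[cmp$groups["comparison"]]]),
    "",
    "| Parameter | Reference mean (SD) | Comparison mean (SD) | % diff |",
    "|---|---|---|---|",
    sprintf("| %s | %.3g (%.3g) | %.3g (%.3g) | %d%% |",
            p$parameter, p$ref_mean, p$ref_sd, p$cmp_mean, p$cmp_sd,
            round(p$percent_difference)),
    "",
    sprintf("P-values are %s (Mann-Whitney U, two-sided).",
            if (cmp$p_adjust == "none") "uncorrected"
            else "Benjamini-Hochberg adjusted"))
  sig <- rbind(
    if (nrow(cmp$feature_tests))
      cmp$feature_tests[cmp$feature_tests$significant,
                        c("station", "p")],
    if (nrow(cmp$harmonic_tests))
      cmp$harmonic_tests[cmp$harmonic_tests$significant,
                         c("station", "p")])
  if (!is.null(sig) && nrow(sig)) {
    lines <- c(lines, "", sprintf("%d test(s) significant at p < %.2f.",
                                  nrow(sig), cmp$alpha))
  }
  lines
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param file YAML path.
#' @return `file` / the configuration.
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$stations <- as.list(x$stations)
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- yaml::read_yaml(file)
  x$stations <- data.frame(station = x$stations$station,
                           z_mm = x$stations$z_mm)
  do.call(pipeline_config, x)
}
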