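# Slice-wise geometry of cord, dura and subarachnoid space from a labelled
# segmentation.
#
# Areas and perimeters come from the 0.5-level iso-contour of each label's
# indicator function after a light binomial pre-smoothing. On binary masks a
# raw marching-squares contour overestimates the perimeter of smooth shapes
# by ~6% (and voxel-edge counting by up to ~27%); the [1 2 1]/4 smoothing
# restores sub-voxel accuracy (<1.5% perimeter, <0.5% area error on circles
# at 0.4 mm voxels).

#' Labelled segmentation volume of the spinal canal
#'
#' Container for a voxelized segmentation: label 1 = spinal cord, label 2 =
#' CSF space (inside the dura, outside the cord), 0 = background. The dura
#' lumen is the union of labels 1 and 2. Axial layer k sits at
#' `z = (k - 1) * dz` mm, with the foramen magnum (FM) at the `fm_index`
#' layer and the dural sac end at `sac_index`.
#'
#' @param labels Integer 3-D array `[x, y, z]` with values 0, 1, 2.
#' @param spacing_mm Voxel spacing `(dx, dy, dz)` in mm.
#' @param fm_index,sac_index Axial layer indices of the FM and the caudal
#'   end of the dural sac (`fm_index < sac_index`).
#' @return An object of class `segmentation_volume`.
#' @export
segmentation_volume <- function(labels, spacing_mm,
                                fm_index = 1L,
                                sac_index = dim(labels)[3]) {
  stopifnot(length(dim(labels)) == 3,
            all(labels %in% c(0L, 1L, 2L)),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            fm_index >= 1, sac_index <= dim(labels)[3],
            fm_index < sac_index)
  structure(
    list(labels = labels, spacing_mm = as.numeric(spacing_mm),
         fm_index = as.integer(fm_index),
         sac_index = as.integer(sac_index)),
    class = "segmentation_volume"
  )
}

#' @export
print.segmentation_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "Segmentation volume: %d x %d x %d voxels at %.3g x %.3g x %.3g mm (FM layer %d, sac layer %d)\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    x$fm_index, x$sac_index))
  invisible(x)
}

# axial position (mm below FM) of each layer
.layer_z <- function(seg) {
  (seq_len(dim(seg$labels)[3]) - seg$fm_index) * seg$spacing_mm[3]
}

# separable [1 2 1]/4 binomial smoothing with replicated borders
.binomial_smooth <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m <- (m[c(1, seq_len(nr - 1)), , drop = FALSE] + 2 * m +
          m[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]) / 4
  (m[, c(1, seq_len(nc - 1)), drop = FALSE] + 2 * m +
     m[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]) / 4
}

.poly_area <- function(x, y) {
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

.poly_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# Area (cm^2) and perimeter (cm) of a binary in-plane mask from its
# smoothed 0.5-level contour. dx/dy in cm.
.mask_metrics <- function(mask, dx_cm, dy_cm) {
  if (!any(mask)) return(list(area = 0, perimeter = 0, empty = TRUE))
  xs <- (seq_len(nrow(mask)) - 1) * dx_cm
  ys <- (seq_len(ncol(mask)) - 1) * dy_cm
  sm <- .binomial_smooth(mask * 1)
  cl <- contourLines(xs, ys, sm, levels = 0.5)
  if (length(cl) == 0) return(list(area = 0, perimeter = 0, empty = TRUE))
  area <- sum(vapply(cl, function(p) .poly_area(p$x, p$y), 0))
  per <- sum(vapply(cl, function(p) .poly_perimeter(p$x, p$y), 0))
  list(area = area, perimeter = per, empty = FALSE)
}

#' Geometric parameters of one axial slice
#'
#' Extracts cross-sectional areas (cm^2), perimeters (cm) and hydraulic
#' diameter (cm) of cord, dura and SSS at axial position `z_mm` (nearest
#' voxel layer). The SSS quantities follow the duct-flow identities
#' `A_cs = A_d - A_c`, wetted perimeter `P_cs = P_c + P_d`, and
#' `D_H = 4 A_cs / P_cs`. Below the conus the cord label may be empty, in
#' which case `A_cs = A_d` and `P_cs = P_d`. A slice with an empty dura
#' lumen is flagged `missing` (and is excluded, not zero-filled, by
#' [geometry_profile()]).
#'
#' @param seg A [segmentation_volume()].
#' @param z_mm Axial position in mm below the FM.
#' @return A one-row data.frame: `z_mm`, `a_c`, `a_d`, `a_cs`, `p_c`,
#'   `p_d`, `p_cs`, `d_h`, `missing`.
#' @export
extract_slice_geometry <- function(seg, z_mm) {
  stopifnot(inherits(seg, "segmentation_volume"))
  zl <- .layer_z(seg)
  if (z_mm < zl[seg$fm_index] - 1e-9 || z_mm > zl[seg$sac_index] + 1e-9)
    stop("z outside the FM..dural-sac range")
  k <- which.min(abs(zl - z_mm))
  sl <- seg$labels[, , k]
  dx <- mm_to_cm(seg$spacing_mm[1])
  dy <- mm_to_cm(seg$spacing_mm[2])
  lumen <- .mask_metrics(sl >= 1L, dx, dy)
  if (lumen$empty) {
    return(data.frame(z_mm = z_mm, a_c = NA_real_, a_d = NA_real_,
                      a_cs = NA_real_, p_c = NA_real_, p_d = NA_real_,
                      p_cs = NA_real_, d_h = NA_real_, missing = TRUE))
  }
  cord <- .mask_metrics(sl == 1L, dx, dy)
  a_cs <- lumen$area - cord$area
  p_cs <- lumen$perimeter + cord$perimeter
  data.frame(z_mm = z_mm,
             a_c = cord$area, a_d = lumen$area, a_cs = a_cs,
             p_c = cord$perimeter, p_d = lumen$perimeter, p_cs = p_cs,
             d_h = if (a_cs > 0) 4 * a_cs / p_cs else NA_real_,
             missing = FALSE)
}

#' Geometry profile along the spine
#'
#' Slice geometry every `spacing_mm` (default 1 mm) from the FM to the end
#' of the dural sac, with normalized axial distance `z_norm = z / L`,
#' integrated volumes `V = sum(A dz)` and surface areas `SA = sum(P dz)`
#' for cord, dura and SSS. Missing slices (empty dura contour) are linearly
#' interpolated over in the profile and flagged in the `missing` column;
#' `d_h` is recomputed from the interpolated areas and perimeters.
#'
#' @param seg A [segmentation_volume()].
#' @param spacing_mm Axial sampling interval in mm.
#' @return An object of class `geometry_profile`: list with `slices`
#'   (data.frame `z_mm`, `z_norm`, `a_c` ... `d_h`, `missing`),
#'   `v_c`, `v_d`, `v_cs`, `sa_c`, `sa_d`, `sa_cs` (cm^3 / cm^2),
#'   `length_mm`, `spacing_mm`.
#' @export
geometry_profile <- function(seg, spacing_mm = 1) {
  stopifnot(inherits(seg, "segmentation_volume"), spacing_mm > 0)
  zl <- .layer_z(seg)
  L <- zl[seg$sac_index]
  z <- seq(zl[seg$fm_index], L, by = spacing_mm)
  rows <- do.call(rbind, lapply(z, function(zi) extract_slice_geometry(seg, zi)))
  # interpolate across missing slices (never zero-fill)
  for (col in c("a_c", "a_d", "a_cs", "p_c", "p_d", "p_cs")) {
    v <- rows[[col]]
    if (anyNA(v)) {
      ok <- !is.na(v)
      if (sum(ok) < 2) stop("too few valid slices to build a profile")
      rows[[col]] <- approx(z[ok], v[ok], xout = z, rule = 2)$y
    }
  }
  rows$d_h <- ifelse(rows$a_cs > 0, 4 * rows$a_cs / rows$p_cs, NA_real_)
  rows$z_norm <- rows$z_mm / L
  rows <- rows[, c("z_mm", "z_norm", "a_c", "a_d", "a_cs",
                   "p_c", "p_d", "p_cs", "d_h", "missing")]
  dz_cm <- mm_to_cm(spacing_mm)
  structure(
    list(slices = rows,
         v_c = sum(rows$a_c) * dz_cm,
         v_d = sum(rows$a_d) * dz_cm,
         v_cs = sum(rows$a_cs) * dz_cm,
         sa_c = sum(rows$p_c) * dz_cm,
         sa_d = sum(rows$p_d) * dz_cm,
         sa_cs = sum(rows$p_cs) * dz_cm,
         length_mm = L, spacing_mm = spacing_mm),
    class = "geometry_profile"
  )
}

#' @export
print.geometry_profile <- function(x, ...) {
  cat(sprintf(
    paste0("Geometry profile: %d slices over %.0f mm\n",
           "  mean A_cs %.3f cm^2 | mean P_cs %.3f cm | mean D_H %.3f cm\n",
           "  V_c %.1f | V_d %.1f | V_cs %.1f cm^3\n"),
    nrow(x$slices), x$length_mm,
    mean(x$slices$a_cs), mean(x$slices$p_cs),
    mean(x$slices$d_h, na.rm = TRUE),
    x$v_c, x$v_d, x$v_cs))
  invisible(x)
}

#' Slice value nearest to an axial position
#'
#' Convenience accessor used when a station's cross-sectional area is
#' needed from a profile.
#'
#' @param profile A [geometry_profile()].
#' @param z_mm Axial position (mm).
#' @param what Column of the slice table, default `"a_cs"`.
#' @return The value at the nearest profiled slice.
#' @export
profile_value_at <- function(profile, z_mm, what = "a_cs") {
  stopifnot(inherits(profile, "geometry_profile"))
  i <- which.min(abs(profile$slices$z_mm - z_mm))
  profile$slices[[what]][i]
}
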