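# Unit conventions, shared constants, and the measurement-station table.
#
# Internal units: lengths cm, areas cm^2, volumes cm^3, flow cm^3/s,
# velocity cm/s, time s. Axial coordinates along the spine are the one
# exception and are kept in mm (z = 0 at the foramen magnum, increasing
# caudally). All conversions go through the helpers below.

#' Sign carried by caudally directed flow
#'
#' Caudal (downward) CSF flow is negative throughout the package, so the
#' systolic peak of a flow waveform is its most negative sample. Exported so
#' that analysis code can state the convention instead of hard-coding `-1`.
#'
#' @return `-1`.
#' @export
caudal_sign <- function() -1

#' Kinematic viscosity of CSF
#'
#' CSF viscosity is conventionally taken equal to that of water at body
#' temperature (37 C): nu = mu / rho = 0.00693 cm^2/s.
#'
#' @return Kinematic viscosity in cm^2/s.
#' @export
csf_kinematic_viscosity <- function() 0.00693

#' Default axial measurement stations
#'
#' The six vertebral levels at which through-plane velocity is acquired,
#' with nominal axial positions (mm below the foramen magnum) used by the
#' synthetic generator and the pipeline defaults.
#'
#' @return A data.frame with columns `station` and `z_mm`.
#' @export
#' @examples
#' csf_stations()
csf_stations <- function() {
  data.frame(
    station = c("FM", "C2-C3", "C5-C6", "T4-T5", "T11-T12", "L3-L4"),
    z_mm = c(0, 45, 105, 220, 360, 460),
    stringsAsFactors = FALSE
  )
}

mm_to_cm <- function(x) x / 10
cm_to_mm <- function(x) x * 10

# near-equality helper used by validators
.is_close <- function(a, b, tol = 1e-9) abs(a - b) <= tol
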