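---
title: "Quantifying spinal CSF dynamics: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spinal CSF dynamics: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfhydro)
```

## The measurement problem

Cerebrospinal fluid in the spinal subarachnoid space (SSS) — the annular
sheet of fluid between the spinal cord and the dura — pulsates with the
cardiac cycle: a short, caudally directed systolic surge followed by a
longer cranial diastolic return, with essentially zero net flow over a
cycle. Two MRI acquisitions characterize this system non-invasively: a
high-resolution anatomical scan that is segmented into cord and
dura-bounded lumen, and cardiac-gated phase-contrast velocity images at a
handful of axial stations. From these, the package derives the geometric
substrate (areas, perimeters, volumes), the pulsatile flow waveforms, and
dimensionless hydrodynamic characterizations that matter for intrathecal
solute transport: Reynolds number (is the flow laminar?), Womersley
number (how blunt is the velocity profile?), and pulse wave velocity
(how stiff is the compliant canal?).

Throughout, caudal flow is negative (`caudal_sign()`), lengths are cm,
flow is cm³/s, and axial position z is in mm below the foramen magnum
(FM), increasing caudally to the closed end of the dural sac.

## Geometry from labelled voxels

At every axial position (1 mm spacing by default) the cord and
dura-lumen indicators are contoured at the 0.5 level after a separable
[1 2 1]/4 binomial smoothing, and areas/perimeters are taken from the
resulting polygons (shoelace formula and arc length). The smoothing step
is what makes the estimate sub-voxel: on binary masks a raw
marching-squares contour overestimates the perimeter of a circle by
about 6% (and voxel-edge counting by up to 27%), whereas the smoothed
contour is accurate to well under 1.5% in perimeter and 0.5% in area at
0.4 mm voxels. The SSS quantities follow the internal-duct identities

- `A_cs = A_d − A_c`,
- wetted perimeter `P_cs = P_c + P_d` (both walls wet the flow),
- hydraulic diameter `D_H = 4 A_cs / P_cs`,

which the code computes *by construction* from the per-label contours, so
the additive identities hold exactly. Degenerate slices are handled
explicitly: an empty cord label (below the conus) gives `A_cs = A_d`; an
empty dura contour marks the slice missing, and profiles interpolate over
missing slices rather than zero-filling them, which would corrupt `D_H`.
Volumes and surface areas are slice sums, `V = Σ A Δz`, `SA = Σ P Δz`.

Slicing is along the image axial axis. The phantoms have a straight canal
axis, making this exact; for curved clinical anatomies a centerline-based
reslicing would be required before these functions apply, and that
limitation is deliberate (see *Limitations*).

## Flow and waveform processing

Volumetric flow is the voxel-area-weighted sum of through-plane
velocities over the CSF mask, `Q(t) = A_voxel Σ v(t)`. Each waveform is
offset-corrected by subtracting its time mean — gating offsets and eddy
currents otherwise leave a spurious net flow — after which the systolic
peak is `min Q` and the diastolic peak `max Q`.

Retrospective gating from pulse oximetry leaves an arbitrary per-subject
phase origin. The package estimates it once per subject, at C2–C3, as the
time of the most negative cyclic central-difference derivative (the
steepest systolic descent), and applies the same circular shift to every
station, preserving inter-station delays exactly. Alignment is performed
*before* any extension because a circular shift is only well-defined on a
periodic signal; it provably cannot change harmonic magnitudes, only
phases, and the test suite asserts this.

For cross-subject comparison all waveforms are resampled onto a fixed
1280 ms window at 10 ms (128 samples). Cycles shorter than the window are
extended through diastole by holding the terminal sample
(`pad = "hold"`): late diastole is near-steady, and zero-padding would
inject a step discontinuity into the spectrum. Spectra are reported at
harmonics 1–7 *of the window* (bin k ↔ k/1.28 s ≈ 0.78 k Hz), not of the
subject's own cardiac frequency; all subjects share the grid, which is
what makes the per-harmonic group tests well-defined, but it means a
subject's cardiac fundamental generally does not coincide with bin 1.
Magnitudes use the one-sided 2/N scaling (a bin-aligned sinusoid of
amplitude a reports magnitude a). Before the FFT, each station is divided
by the subject's C2–C3 average flow magnitude. "Average flow rate" is
ambiguous in the literature; the default normalizer is the time mean of
|Q| over the native cycle, with `"peak"` (systolic magnitude) and
`"stroke"` (rectified caudal mean) exposed as alternatives — group
comparisons are invariant to a common rescaling, so the choice mainly
affects the absolute scale of reported harmonics.

## Hydrodynamics

Flow is interpolated in z, linearly per time sample, between stations;
above the most cranial station it is held constant, and below the most
caudal station it tapers linearly to an appended boundary node with Q = 0
at the dural sac end — a closed sac passes no flow. From the resulting
Q(z, t) grid:

- `Re(z) = |Q_sys(z)| D_H(z) / (ν A_cs(z))`, flagged laminar when
  Re < 2300. The systolic magnitude is used so Re is positive while
  `Q_sys` is negative.
- `α(z) = D_H(z) √(ω/ν)`. Two conventions for the pulsation frequency are
  implemented because parts of the CSF literature print `ω = 2/T` where
  the standard angular frequency is `2π/T` (most plausibly a typesetting
  loss of π). The default is `"angular"`; `"literature"` reproduces the 2/T
  variant. Published spine-averaged Womersley values cannot adjudicate
  between them, because they average unreported per-slice values.
- PWV is 1/slope of the ordinary least-squares fit of the peak-systolic
  arrival time on z. Arrival time is the measured, quantized (10 ms)
  quantity, so it is the regressand by default; `fit = "z_on_t"` is
  exposed for comparison. The fit uses only z where local peak-to-peak
  flow exceeds the pulsation threshold **and**, by default, only the
  axial span actually covered by stations: below the last station the
  interpolant is a pure amplitude taper whose arrival time is constant,
  which would bias the slope toward zero (infinite PWV). Zero slope is
  reported as an infinite-PWV flag; negative slopes are reported with
  diagnostics, never clipped.

The kinematic viscosity defaults to water at body temperature,
ν = 0.00693 cm²/s, and is configurable.

## Cohort statistics

Per-subject scalars are equal-weight means over the 1 mm slices (whether
published spine averages weight slices equally or by segment is unstated;
equal weighting is the declared choice here), plus volume/surface totals.
Groups are compared descriptively (mean ± sample SD, percent difference
`100 (ref − cmp)/ref`) and inferentially with two-sided Mann–Whitney U
tests — exact by null enumeration for small tie-free samples, otherwise
the normal approximation with tie and continuity corrections — reported
with the `U = min(U_A, U_B)` convention. No multiplicity correction is
applied by default, as is common for exploratory cohort comparisons of
this size; Benjamini–Hochberg
is available (`p_adjust = "BH"`) and the outputs label p-values as
uncorrected. A subject whose peak-to-peak flow is below the pulsation
threshold (default 0.1 cm³/s) at every station is excluded from flow and
hydrodynamic analyses but keeps its geometric summary, with a
machine-readable reason — mirroring how a near-zero-flow patient must be
handled in practice.

## The synthetic phantom: what it emulates, and what it does not

Because patient images cannot ship with the package, a generator stands
in for them. It emulates the *statistical structure* the analysis needs:

- **Geometry**: a straight canal with concentric elliptical cord and dura
  sections; radii are monotone-cubic interpolations of control points
  with cervical and lumbar enlargements and a conus/filum taper. The dura
  uses aspect ratio 1.982: circular sections cannot reproduce realistic
  wetted perimeters at realistic areas (the dura is laterally elongated),
  and this single aspect parameter closes that gap. The default knots
  were calibrated once, at design time, so the analytic spine averages
  match reported healthy-adult values: A_c 0.35, A_d 2.13, A_cs 1.78 cm²,
  P_cs 7.53 cm, V_cs ≈ 107 cm³. Cord perimeter lands at ~2.0 cm — a
  concentric model cannot simultaneously match published cord area and
  the slightly smaller published cord perimeter, which averages over
  non-convex real sections.
- **Flow**: a zero-mean three-harmonic waveform (T = 956 ms; sharp
  caudal systolic trough of 4.23 cm³/s at 0.16 T; systole/diastole peak
  ratio ≈ 1.9) propagating caudally at a prescribed wave speed (default
  347 cm/s) with exponential amplitude decay (default: to 25% at the
  L3–L4 level), spread uniformly over the annulus (plug profile — the
  pipeline integrates flow, not profile shape; an annular-Poiseuille
  option exists), plus Gaussian velocity noise (default SD 0.3 cm/s,
  configurable; per-station SNR of real acquisitions is rarely reported,
  so this is an order-of-magnitude choice) and optional VENC wrap at
  10 cm/s.
- **Cohorts**: per-subject normal jitter of radius scale (SD 6%),
  amplitude scale (SD 12%), PWV scale (SD 15%) and cycle duration
  (956 ± 138 ms, truncated to [600, 1264] ms), applied after per-group
  modifiers (amplitude scale, PWV, dura radius scale, ...). The jitter
  SDs are fixed design constants chosen of the order of the reported
  measurement repeatability for these quantities (peak-flow CV of a few
  to ~15% across published phantom and inter-operator studies), so that
  group contrasts of the published magnitude remain resolvable at the
  published sample sizes. All randomness flows through one seed; a cohort
  is a deterministic function of it.

What the phantom deliberately does **not** model: k-space/complex-signal
noise, eddy-current and Maxwell phase errors, gating jitter, nerve roots
and denticulate ligaments, canal curvature, and focal stenoses. Passing
tests on phantoms therefore validate the *analysis chain* — geometry
extraction, integration, alignment, spectral analysis, interpolation,
fitting, statistics — not the MRI physics upstream of it.

## Numerical choices and degenerate inputs

- Voxel centres exactly on an ellipse boundary are included with a 1e-9
  relative slack, so lattice-coincident radii do not flip voxels on
  last-bit interpolation noise.
- Steepest-descent ties break toward the earliest sample; a flat
  reference waveform is an error naming the tie count.
- Peak times are read off the sampled grid (no sub-sample refinement):
  the gated acquisition defines its own temporal resolution.
- The interpolation grid carries the geometry profile's z axis; the
  boundary node at the sac end is appended only when no station sits
  there.
- `extend_and_resample` clamps interpolation at the native cycle's last
  sample, so floating-point grid edges cannot produce NA.
- Exact U tests are used whenever the pooled sample is tie-free and
  |A|·|B| ≤ 10⁶; identical samples yield p = 1.

Problem sizes used by the validation suite are deliberate choices: the
default phantom is analyzed at full scale (601 slices, six stations, 30
phases), PWV recovery is checked at 200–600 cm/s on noise-free phantoms
(recovered within 5%; the 10 ms arrival grid is the limiting factor), the
null calibration of the U test uses 1000 simulated cohort pairs, and the
end-to-end sign-consistency property uses 20 simulated cohorts of
10 vs 8 subjects.

## Known limitations

- Straight-axis slicing only; curved spines need centerline reslicing
  first.
- The velocity-weighted spine averages (U_sys, Re) of the default phantom
  run lower than published cohort means: real CSF flow peaks where the
  canal is narrow, a spatial correlation the exponential amplitude-decay
  model reproduces only weakly.
- VENC wrap is generated and can be detected by its signature, but it is
  not repaired.
- Harmonics are tied to the fixed 1280 ms window; interpreting a given
  harmonic as "the k-th cardiac harmonic" is only approximate and
  subject-dependent.
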