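# csfhydro

Quantification of pulsatile cerebrospinal fluid (CSF) dynamics in the
spinal subarachnoid space (SSS) from MRI-derived inputs: a labelled
segmentation of the spinal canal (cord / CSF / background) and
cardiac-gated through-plane velocity series at a small set of axial
stations (FM, C2–C3, C5–C6, T4–T5, T11–T12, L3–L4). It is aimed at
researchers studying intrathecal solute transport and CSF-based disease
markers, where slice-wise geometry and pulsatile-flow hydrodynamics feed
drug-dispersion models and group comparisons.

## What it computes

**Geometry** at 1 mm axial intervals from the foramen magnum (z = 0) to
the end of the dural sac, by sub-voxel iso-contouring of each label:

- cross-sectional areas `A_cs = A_d − A_c`, wetted perimeter
  `P_cs = P_c + P_d`, hydraulic diameter `D_H = 4 A_cs / P_cs`;
- integrated volumes `V = Σ A Δz` and surface areas `SA = Σ P Δz`.

**Flow** per station: volumetric flow by voxel integration
`Q(t) = A_voxel Σ v_voxel(t)`, offset-corrected so net flow is 0 over the
cycle. Caudal flow is negative, so the systolic peak is `min Q`. Feature
points: `(Q_sys, t_sys)`, `(Q_dia, t_dia)`, and mean velocities
`U = Q / A_cs`.

**Waveform analysis**: subject-wise temporal alignment at C2–C3 (steepest
systolic descent mapped to t = 0, one common shift for all stations),
extension to a 1280 ms window with diastolic hold-padding, resampling at
10 ms, normalization by the C2–C3 average flow magnitude, and FFT
harmonics 1–7 of the common window.

**Hydrodynamics**: flow interpolated along the spine onto a
1 mm × 10 ms grid with a closed-sac boundary (Q = 0 at the dural sac);
Reynolds number `Re = |Q_sys| D_H / (ν A_cs)` with the laminar criterion
Re < 2300; Womersley number `α = D_H √(ω/ν)` (both `ω = 2π/T` and the
literature variant `ω = 2/T` are available); pulse wave velocity as the
inverse slope of the least-squares fit of peak-systolic arrival time on
axial position.

**Cohort statistics**: spine-averaged descriptive tables (mean ± SD per
group), percent differences, and two-sided Mann–Whitney U tests (exact
for small tie-free samples) of feature points and harmonics, uncorrected
by default.

A synthetic phantom generator (`phantom_spec()`, `make_phantom_geometry()`,
`make_pcmri_series()`, `make_cohort()`) produces voxelized annular
geometries with cervical/lumbar enlargements and propagating pulsatile
velocity fields with known ground truth (wave speed, amplitude decay,
noise), so the entire chain is testable without patient data.

## Worked example

```r
library(csfhydro)

# a control-like phantom subject, noise-free
spec <- phantom_spec(noise_sd = 0, pwv_true = 475)
seg  <- make_phantom_geometry(spec)
st   <- csf_stations()
flow <- setNames(lapply(st$z_mm, function(z) make_pcmri_series(spec, z)),
                 st$station)

summary <- analyze_subject(list(id = "P1", group = "phantom",
                                seg = seg, flow = flow), details = TRUE)
geometry_profile(seg)
attr(summary, "details")$hydro$pwv
```

prints

```
Geometry profile: 601 slices over 600 mm
  mean A_cs 1.780 cm^2 | mean P_cs 7.581 cm | mean D_H 0.918 cm
  V_c 20.8 | V_d 127.7 | V_cs 107.0 cm^3
PWV: 476.7 cm/s (slope 0.0021 s/cm, R^2 0.937, n = 461)
```

i.e. the voxelized geometry reproduces the phantom's analytic
spine-averaged SSS cross-section (1.78 cm², wetted perimeter 7.53 cm)
within discretization error, and the prescribed wave speed of 475 cm/s is
recovered within 0.4% from the 10 ms arrival-time grid.

The full study-style analysis is the numbered scripts under `analysis/`
(simulate cohort → geometry → flow/waveforms → hydrodynamics → group
comparison), each writing its tables under `results/`. For example
`analysis/04_hydrodynamics.R` reports, for the default simulated cohort
of 10 controls vs 8 ALS-like subjects:

```
All flow laminar (Re < 2300): TRUE; max per-slice Re 277.
PWV: control 372 cm/s, ALS-like 431 cm/s (recovered within 9.7% of truth on average).
```

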