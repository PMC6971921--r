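Package: csfhydro
Title: Quantification of Cerebrospinal Fluid Dynamics in the Spinal
    Subarachnoid Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify pulsatile cerebrospinal fluid (CSF) dynamics
    in the spinal subarachnoid space from labelled segmentations and
    cardiac-gated through-plane velocity images. Computes slice-wise
    geometry (cross-sectional areas, wetted perimeters, hydraulic diameter)
    at 1 mm axial intervals, voxel-integrated volumetric flow waveforms,
    spectral (harmonic) waveform analysis on a common 1280 ms / 10 ms grid,
    hydrodynamic characterization (Reynolds number, Womersley number, pulse
    wave velocity from peak-systolic arrival times), and nonparametric
    cohort comparison. Includes a synthetic phantom and cohort generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml,
    withr,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
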