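Package: aosim
Title: Sensorless Adaptive Optics and 3D Structured Illumination Microscopy Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A Fourier-optics virtual microscope for developing and validating
    adaptive-optics (AO) control methods for upright 3D structured illumination
    microscopy (3D-SIM). Implements Noll-indexed Zernike wavefront machinery,
    scalar pupil/PSF/OTF computation, seeded specimen phantoms with
    depth-dependent aberration models and a deformable-mirror model, sensorless
    modal aberration correction by per-mode bias scanning with a noise-aware
    Fourier image-quality metric, multi-position aberration correction (MPAC)
    by per-depth linear fitting, deformable-mirror remote focusing with
    two-step calibration, raw SIM stack generation, acquisition planning, and
    resolution estimation (bead FWHM, spectral OTF-support cutoffs,
    modulation-contrast QC). Everything runs against synthetic scenes, so no
    hardware and no external data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    pracma,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
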