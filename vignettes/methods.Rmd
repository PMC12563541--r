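---
title: "Simulating sensorless adaptive optics for deep 3D-SIM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sensorless adaptive optics for deep 3D-SIM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aosim)
```

## Why a virtual microscope

Structured illumination microscopy (3D-SIM) doubles lateral and axial
resolution but is unusually sensitive to optical aberrations: the Wiener
reconstruction mixes frequency components whose relative phases an aberrated
transfer function corrupts, so imaging deeper than about 10 µm into tissue
produces artefacts rather than resolution. Adaptive optics (AO) with a
deformable mirror (DM) conjugated to the objective's back focal plane can
correct sample-induced aberrations and, with a different mirror shape, move
the focal plane without moving the specimen (remote focusing). Developing
and validating the *control* side of such a system — metric-based sensorless
correction, per-depth correction interpolation, refocusing calibration,
acquisition sequencing — does not require hardware: every procedure can be
exercised against a Fourier-optics simulation with known ground truth.
`aosim` is that test bench. Every method in the package runs against seeded
synthetic scenes, so all claims in the test suite are checked against known
injected truths.

## The optical model

**Scalar diffraction.** Image formation uses the scalar pupil model: the
system is characterised by a complex pupil function on the unit disk, with
uniform amplitude inside the aperture (radius `NA/λ` in frequency space) and
phase given by a Zernike expansion. The intensity PSF at axial offset `z` is
the squared modulus of the 2D Fourier transform of the pupil multiplied by
the exact high-NA defocus factor `exp(2πi (n/λ) z √(1 − (NA ρ/n)²))`; a
parabolic low-NA approximation is available behind a flag. At NA 1.1 a
vectorial model would be more accurate in absolute terms; the scalar model is
a deliberate simplification, adequate for testing correction logic whose
inputs and outputs are Zernike coefficients, and is declared as an accuracy
caveat rather than hidden. The default configuration is a 60×/1.1 NA
water-immersion system (n = 1.33) with 488/525 nm excitation/emission and
80 × 125 nm voxels.

**Conventions, fixed in one place.** Zernike modes use Noll single
indexing with RMS normalisation: a coefficient of `a` radians contributes
exactly `a` radians RMS of wavefront phase, and orthonormality makes modal
amplitudes add in quadrature. Amplitudes are phase radians at a declared
reference wavelength (emission, 525 nm, by default) — the rad ↔ nm wavefront
conversion is explicit (`zv_rad_to_nm()`) because "radians" is otherwise
ambiguous across channels. FFT arrays keep DC at the first element
internally and are shifted to centred layout only at container boundaries;
frequency axes are reported in µm⁻¹. The pupil grid defaults to 256 samples
(`pupil_grid_size`), which at default sampling leaves more than two-fold
zero padding around the aperture; the aperture rim is a hard cut, matching
the analytic model (one-sample anti-aliasing of the rim exists behind a
flag but slightly apodises the aperture, so it is off by default).

**Independent reference.** `debye_psf()` evaluates the same diffraction
integral by direct Gauss–Legendre × uniform-angle quadrature of the pupil,
with no FFT and its own discretisation. The FFT pipeline agrees with it to
better than 1% relative RMS on 64³ volumes, and the Strehl ratio of 1 rad of
primary spherical aberration matches the Maréchal estimate `exp(−σ²)` within
0.05 — both checked in the test suite against this oracle, never against the
pipeline itself.

## The virtual specimen and its imperfections

Phantoms are deterministic functions of `(kind, parameters, seed)`:
sub-resolution bead fields (100 nm diameter by default, the standard
calibration target), curvilinear sub-diffraction filaments emulating
microtubules/ER tubules, and a Voronoi epithelial mosaic emulating
junction-labelled neuroepithelium. Rendering is circular convolution with
the (depth-local) PSF; phantom generators keep structures away from the FOV
edge so periodic wrap-around is immaterial.

Depth-dependent aberrations are affine per mode (`offset + slope · depth`),
reflecting that dominant terms such as spherical aberration grow in
proportion to imaging depth; an optional seeded high-order perturbation
(scaling with depth, so depth 0 returns the offsets exactly) lets tests
model tissue heterogeneity. The DM model applies a correctable mode set,
per-mode fidelity, a hard amplitude clip, and an optional single-exponential
creep of the held shape (off by default; when on, its amplitude and time
constant are explicit parameters). `bypass_dm()` gives the flat-mirror
control arm. Camera noise is Poisson shot noise plus Gaussian read noise
over a constant background; the photon budget is referenced to the *peak of
the unaberrated render of the scene*, so aberrated images are genuinely
dimmer at equal budget. Defaults — 500 peak photons, 2 e⁻ read noise,
5 photons background — were chosen once to make metric optimisation
realistically noisy, and all are overridable.

Structured illumination is the three-beam (0/±1 order) interference
pattern: an axially modulated lateral sinusoid at the beam-offset frequency
plus an unmodulated lateral second harmonic at twice that frequency, with
five phase steps of 2π/5 and three orientations 60° apart. The `freq_frac`
parameter names the *finest* lateral harmonic as a fraction of the emission
incoherent cutoff `2NA/λ_em`; the default 0.8 is a conservative line-width
choice, and its beam-offset frequency (0.4 of the emission cutoff) stays
comfortably inside the excitation coherent cutoff, which is enforced as a
precondition. The modulation depth `m` parameterises the first harmonic
directly — the beam amplitude ratio is derived from it — so the
modulation-contrast QC metric reads back exactly `m` on an unblurred uniform
scene. Because 1 and 2 are not multiples of 5, both harmonics cancel
exactly in the five-phase average: the pseudo-widefield identity
`PWF(stack) == widefield render` holds to numerical precision and ties the
pattern, rendering and analysis modules together in one test.

## Sensorless correction: design choices

The correction engine scans one mode at a time over a bias list (default
`{−1, −0.5, 0, 0.5, 1}` rad; 8 modes × 5 biases = 40 frames), scores each
widefield frame with a Fourier metric, fits a Gaussian-plus-offset to the
(bias, metric) points and takes the fitted mean as the modal correction,
accumulating it before the next mode is scanned. The base mode set is Noll
#5–#11 plus #22: the low-order sample-induced terms plus secondary
spherical, which matters at depth. Stored corrections are the amplitudes
*applied to the DM* (already negated), so the combined correction is the
index-wise sum `system_flat + sample_correction`, measured in that order —
instrument-intrinsic aberrations are corrected first on a sparse bead scene
and sample corrections ride on top.

**The metric.** Total Hann-windowed spectral power in an annulus of the
emission passband (default 0.1–0.8 of `2NA/λ_em`), minus an area-scaled
noise floor estimated from the band just beyond the cutoff — where a
well-sampled image carries no signal, only noise — floored at zero.
Every constant is exposed in `metric_config()`. Optional DC normalisation
makes the metric invariant to global intensity scaling. This is the
standard family of sensorless-AO image metrics; the annulus excludes the
lowest frequencies (dominated by background) and the empty corner of the
spectrum.

**Fit fallbacks.** Nonlinear fits can fail or run away on monotone metric
sequences; if the fit does not converge or its mean lands outside 1.5× the
scanned range, the routine falls back to the best scanned bias and flags
the scan. A correction in which *every* mode fell back raises an error
rather than returning noise.

**Passes and crosstalk.** Mode scan order is ascending Noll index; the
default is a single pass. The Fourier metric couples modes that affect
similar spatial frequencies — most visibly secondary into primary spherical
— so a single pass can leave ~0.1–0.2 rad of per-mode crosstalk after a
large #22 injection even though the combined wavefront is near the metric
optimum; this coupling is a property of the metric's nonlinearity, not of
the fit, and we measured it to be insensitive to the annulus choice. A
second pass, scanning on top of the accumulated correction, removes it
(≤ 0.011 rad recovery error for every base mode at amplitudes up to 1 rad,
noiseless). The recovery-focused tests and the acceptance script therefore
run `passes = 2`; the composition property (a second pass never increases
the residual wavefront RMS on noiseless scenes) is tested separately.

## MPAC and remote focusing

MPAC fits an independent least-squares line per mode through corrections
measured at a few anchor depths (typically two: top and bottom of the
volume) and predicts every other section affinely. On any affine depth
model the prediction is exact; extrapolation beyond the anchors warns but
proceeds, matching the pragmatic two-anchor workflow.

Remote focusing expresses the exact high-NA refocusing phase on the DM's
rotationally symmetric modes {4, 11, 22} — the dominant terms of its
expansion; for the default optics the unexpressed residual stays below
0.05 rad RMS out to ±10 µm and is always reported, never dropped.
Calibration is two-step, precision then accuracy: step one regresses the
achieved axial image peak (centre-of-mass within ±3 voxels of the maximum,
then parabolic sub-voxel refinement, ties toward smaller z) on the
commanded shift and requires R² ≥ 0.99; step two inverts the measured
command-to-shift map with a monotone cubic (Hyman) interpolant, so a DM
that reaches only a fraction of its requested stroke still hits targets
through the lookup. Correction and refocusing patterns are controlled
independently and summed index-wise when used together. The headline
property is stage equivalence: remote and mechanical z-stacks of the same
noiseless bead scene correlate ≥ 0.99 plane by plane across ±5 µm.

## Resolution analysis

Bead FWHM fits 1D Gaussian-plus-offset profiles along x, y and z;
`FWHM = 2√(2 ln 2) σ` exactly, lateral is the x/y mean under an isotropy
assumption. Rejection rules (fit R² < 0.95, FWHM > 3× the diffraction
estimate, neighbour within an exclusion radius) are applied with recorded
reasons. The spectral estimate radially averages log-power in the central
kxy plane (axially: folds ±kz, then averages along kx), normalises each
profile to [0, 1], and reads the cutoff where the normalised log-power
first drops below 0.01; resolution is exactly the inverse of that
frequency. Two declared normalisation details: the noise floor is the
median log-power of the top 10% frequency band, and it is never taken more
than 60 dB below the profile maximum — noiseless simulated volumes
otherwise have a floor set by FFT leakage a dozen decades down, which would
make the 1% threshold meaningless; real noisy data sit well inside the cap,
which is then inactive. A Hann window (switchable) suppresses edge leakage.
Since SIM reconstruction itself is out of scope, the doubled-support
rendering used in resolution tests images the scene through the widefield
PSF of a system with twice the frequency cutoff (half the wavelength): an
OTF of doubled support with undiminished pass-band amplitude. That is a
closer idealisation of a *well-reconstructed* SIM volume than, say, the
squared widefield PSF — whose autocorrelation OTF, while formally of
doubled support, decays so steeply that threshold-based support estimators
never see the outer half — because Wiener reconstruction reweights the
recovered pass-band to roughly uniform amplitude. It requires sampling fine
enough for the doubled support (`voxel_xy ≤ λ_em / (8 NA)`).

## Acquisition bookkeeping

A SIM volume is `5 phases × 3 angles × n_z × n_channels` raw frames
(210 for 2 channels × 7 sections; 1200 per channel at 80 sections), a
widefield volume `n_z × n_channels`; a section series spans
`(n − 1) · step` (16 µm for 129 sections 125 nm apart); a volume takes
`frames / rate` seconds (10.5 s at 20 fps for 210 frames). Default frame
ordering is phase-fastest — the SI phase step is the cheapest state change
— with arbitrary permutations supported, including on TIFF export/import.
Trigger tables resolve one row per frame to a finite, per-section
deduplicated set of DM patterns (MPAC prediction + refocusing command),
mirroring a driver that stores patterns ahead of a hardware-triggered
acquisition. Settle times are carried as metadata only.

## Problem sizes and what the tests do and don't show

The test suite and acceptance script run at deliberately small scale: 64 px
scope frames with a 128-sample pupil for most closed-loop tests, 128 px
frames for the recovery acceptance runs, 20 noise seeds for the stochastic
medians, 64³ volumes for oracle equivalence. These sizes were chosen so the
whole validation runs comfortably on a laptop while every estimate stays
well-conditioned (the Gaussian optimum, for instance, is located to ~0.002
rad on 128 px frames).

Passing tests show that the *methods* — metric, fit, loop, interpolation,
calibration, bookkeeping — behave correctly on scenes whose ground truth is
known and whose physics is the declared scalar model. They do not show that
a physical microscope achieves any particular resolution: real systems add
vectorial high-NA effects, field-dependent and high-order aberrations,
scattering (which reduces modulation contrast with depth in ways the photon
budget only caricatures), polarisation, and reconstruction artefacts. The
phantom generators emulate geometry, not fluorophore photophysics; noise is
pixel-independent; aberrations are field-constant across the FOV, matching
the single-average-correction regime the methods target.

Other interface notes: the package's functions, the fixture generator and
`run_pipeline()` *are* the command surface — everything is scriptable from
R, so no separate shell entry point is shipped. Known limitations worth
restating: scalar PSF at NA 1.1; locally shift-invariant depth rendering
(each output plane uses its own depth's PSF but a spatially constant one);
no scattering or thick-sample wave propagation; SIM reconstruction is out
of scope, so resolution doubling is demonstrated on the constructed
doubled-support rendering, not on reconstructed data.
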