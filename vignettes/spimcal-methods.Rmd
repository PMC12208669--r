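---
title: "Design calculus and characterization methods in spimcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design calculus and characterization methods in spimcal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spimcal)
```

## Scope

`spimcal` supports two activities around large field-of-view selective plane
illumination (light-sheet) microscopes: the *design calculus* that relates
lens, sensor, and tissue-expansion parameters to resolution, coverage, and
throughput; and four *image-based characterization pipelines* — bead PSF
field mapping, field-curvature estimation from through-focus grating stacks,
radial distortion profiling from dot-grid targets, and camera SNR
comparison. Because the characterization pipelines normally require a
physical instrument, the package ships seeded synthetic-scene generators
with paired ground truth, so every pipeline can be validated closed-loop on
a desk.

## The design calculus

The throughput of an optical system is summarized by its etendue,

$$G = \frac{\pi}{4}\,(\mathrm{FOV}\cdot\mathrm{NA})^2 \; [\mathrm{mm}^2],$$

which is proportional to the number of resolvable elements: doubling either
the field-of-view diameter or the numerical aperture quadruples the
accessible information. The remaining quantities are elementary but easy to
get inconsistent, so they are centralized:

* object-space sampling = pixel pitch / magnification (µm/px);
* Nyquist-limited resolution = 2 × sampling;
* voxel rate of a rolling-shutter sensor = row width / line time;
* effective resolution in native tissue = optical resolution / linear
  expansion factor; native extents divide the same way;
* light collection scales as NA², so two apertures compare as
  `(na_ref/na_test)^2`;
* depth of field uses the classical convention λ·n/NA² (a convention, not a
  measurement — it only sets the unit in which field curvature is
  reported);
* tile plans use the minimal axis-aligned grid with at least the requested
  fractional overlap; the z axis is covered by the stage scan, not tiling.

Worth noting: for the reference instrument's own lens (16.8 mm FOV,
NA 0.305) this formula gives G = 20.62 mm², while the manufacturer-style
figure usually quoted for it is 19.65 mm². The package reports the formula
value and leaves the discrepancy visible rather than special-casing one
lens.

Reported values follow the mixed rounding conventions used in practice:
voxel rates truncate to integer megavoxels/s, lengths round half-up at the
printed precision. Raw unrounded values are always retained in the report
objects; only `print()` methods and `*_reported` fields round.

## Synthetic scenes and what they do (and do not) emulate

All generators take an explicit seed and are bit-reproducible; sub-streams
for noise are derived deterministically from the scene seed.

**Camera noise** is offset + gain × Poisson(photons) + Gaussian read noise.
On a uniform patch this reproduces the photon-transfer identity
`var = gain · (mean − offset) + read_noise²`, which the test suite checks
at 10⁶ samples. Fixed-pattern noise (PRNU/DSNU) is deliberately not
modeled.

**Bead phantoms** render sub-resolution fluorescent microspheres as
*cell-averaged* anisotropic Gaussians at sub-voxel positions — each voxel
receives the integral of the Gaussian over its cell, not a point sample.
A Gaussian with matched FWHM is the standard surrogate for a PSF whose
FWHM is the quantity of interest; diffraction side lobes are not modeled.
Placement is greedy rejection sampling with a minimum mutual separation
(default 3× FWHM); an impossible density request is refused rather than
silently violated.

**Through-focus grating stacks** emulate scanning a Ronchi ruling through
a curved focal surface. Each frame is a binary square wave convolved with
a Gaussian whose width grows with local defocus, `sigma(|z − z0(x, y)|)`,
so per-region contrast peaks at the local best focus and decays
symmetrically — with a linear blur model the contrast-versus-depth curve
is very nearly Gaussian in z, which is exactly the model the analysis
fits. Numerical choices: the focus surface is evaluated piecewise-constant
on a configurable rendering-block grid (the validation suite renders on
blocks 2× finer than the 16×16 analysis ROIs, so each ROI spans a genuine
spread of focus depths);
for integer grating periods the exact erf-form profile is tabulated on a
dense 2048-point blur grid and linearly interpolated (error ≪ one count);
where the fundamental's attenuation `exp(−2π²σ²/p²)` falls below 10⁻⁶ the
field is rendered flat at the mean level. `quantize = TRUE` stores integer
counts, as a real ADC would, halving memory for the multi-gigavoxel
stacks.

**Dot grids** are dark dots on a bright background (a trans-illuminated
target), displaced by the radial model `r_d = r(1 + k1 r² + k2 r⁴)` about
a distortion centre and rendered with a Gaussian edge spread (default
1 px, emulating optical blur of the target edge). Dots pushed out of frame
by the requested distortion are refused.

What passing closed-loop tests shows is that the *estimators* are unbiased
and precise under the stated image-formation models; it does not certify
any physical instrument, whose PSF, ghost reflections, illumination
nonuniformity, and sample-induced aberrations are outside these models.

## PSF quantification

Detection finds 26-connected local maxima above
`median + threshold × MAD`, then applies brighter-wins non-maximum
suppression at a minimum physical separation. Fitting extracts an ROI,
estimates background as the median of the ROI's outer one-voxel shell
(robust to neighbours), refines the centroid, and fits the three 1-D
profiles through the centroid with a *pixel-integrated* Gaussian
(erf-difference). The integrated model matters: fitting a point-sampled
Gaussian to cell-averaged data inflates the width by
`sqrt(1 + 1/(12σ²))` — about 6% at σ = 0.8 px — whereas the integrated fit
recovers the generating width to well under 1%. FWHM = 2√(2 ln 2)·σ.

Beads are flagged rather than dropped: `edge` (ROI clipped), `saturated`
(any ROI voxel at the bit-depth maximum), `clumped` (pair closer than 3×
the smaller of the two mean FWHMs — the smaller, because a contaminated
fit inflates the larger one), `fit_failed`. Field maps bin unflagged beads
on an (x, y) grid and report per-bin mean and SD of lateral
(mean of x and y) and axial FWHM; empty bins are NA, never zero. Bead
averaging is an unweighted mean; fit-quality weighting was considered and
rejected as an unforced assumption.

## Field curvature

The stack is split into a 16×16 ROI grid (remainder pixels join the last
row/column; a 14192×10640 frame gives exactly 887×665 px ROIs). Per-frame
contrast is the percentile form `C = (I95 − I5)/(I95 + I5)` — type-7
(linear-interpolation) percentiles, identical to `stats::quantile` and
invariant under gain changes. The contrast-versus-depth curve is fit with
a Gaussian *plus baseline*: a pure normal density cannot represent the
nonzero background contrast that a real curve has, so the baseline term is
required for an unbiased centre. A fit is invalid when the fitted peak
rises less than 3× the residual RMS above baseline, when the centre
leaves the scanned range, or on non-convergence.

Best-focus depths are radially averaged in ROI rings (8 rings for 16×16;
ring rather than continuous-radius binning, chosen for rotation
invariance on the square grid), referenced to the innermost ring so the
profile is zero at the field centre by construction, and optionally
expressed in depth-of-field units. Wavebands are independent runs; no
joint chromatic fit is attempted.

The per-frame percentile pair for all 256 ROIs is computed in one
compiled pass over the stack using exact order statistics
(`std::nth_element`), bit-identical to the per-frame R definition; the
suite asserts that identity.

## Lens distortion

Dots are segmented by global Otsu threshold and connected components;
border-touching components are rejected and counted. Centroids are
intensity-weighted with weights `(foreground − threshold)⁺` over a padded
bounding box: the weight vanishes continuously on a circular level set of
the dot profile, so sub-pixel truncation does not bias the centroid
(measured bias ~0.001 px on synthetic targets).

The theoretical lattice is anchored on the detected dot nearest the image
centre, with axes estimated from its immediate neighbours — minimal
assumptions, no global lattice fit that would let distortion leak into the
reference (the global fit remains a possible extension). Assignment is
nearest-node and must be injective; collisions flag both dots. Percent
distortion is radial, `100 (r_meas − r_theo)/r_theo`, positive for
pincushion, and is radially averaged in bins. The `k1` estimate fits
`c + k1 r²`; the intercept absorbs residual global lattice-scale
(magnification) error, which is not distortion and would otherwise bias
`k1` by several percent. Tangential residuals stay available in the
assignment table as diagnostics.

## Camera sensitivity

SNR is `(signal − background_mean)/background_noise`, with the signal the
bead's peak voxel (an integrated-intensity mode is available) and the
background statistics from a surrounding annulus that must contain ≥ 100
voxels and exclude other beads. `snr_vs_rate()` simulates the same bead
at several line (dwell) times with photons ∝ dwell and pairs each SNR with
the voxel rate `row_width / line_time`. In the shot-noise regime SNR
scales as √dwell; with read noise it becomes sublinear at low counts. This
exposes the row-parallelism argument directly: at a matched voxel rate a
14192-pixel row integrates ~7× longer than a 2048-pixel row, giving a
higher SNR at the same speed. Printed instrument comparisons between
physical cameras are not reproduced — they require the cameras; sensor
noise parameters here are user-supplied configuration with typical sCMOS
defaults.

## Problem sizes used in the validation suite

The acceptance-style tests run, per seed: a 1,000-bead phantom on an
801×801×80 voxel volume (0.75/0.75/1 µm voxels) with median-FWHM-error and
anisotropy checks; twenty random parabolic/quartic focus surfaces (corner
shifts up to ±50 µm) on 512×512×2000 stacks at 1 µm steps — the full 2 mm
scan of the physical protocol at reduced frame size; dot grids at three
distortion magnitudes spanning `k1·r_max²` from 10⁻⁴ to 10⁻²; and
SNR-versus-dwell over a decade of dwell times. These sizes were chosen as
the smallest at which the estimators' errors are measured against
thresholds with comfortable margin rather than at their asymptotic floor.

## Known limitations

* No diffraction PSF model, pupil functions, or aberration (Strehl)
  accounting; resolution enters only as FWHM.
* No OME-Zarr I/O; stacks are read and written as (Big)TIFF, and voxel
  size must be supplied explicitly when a file carries none.
* Distortion is radial-only (no full Brown–Conrady tangential terms) and
  images are measured, never resampled/undistorted.
* The refractive-index/aberration scaling of deep imaging is noted
  qualitatively in the design discussion but has no quantitative model
  here.
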