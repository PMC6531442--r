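---
title: "Quantifying cortical granule exocytosis from TIRF movies"
author: "cgExoTrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical granule exocytosis from TIRF movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgExoTrack)
```

## The measurement problem

Cortical granules (CGs) are ~200 nm secretory vesicles that accumulate in
a thin layer under the plasma membrane of the mouse egg and fuse with it
after fertilization, releasing enzymes that block polyspermy. Total
internal reflection fluorescence (TIRF) microscopy illuminates only an
evanescent layer above the coverslip whose excitation intensity decays as
$e^{-z/d}$ with a penetration depth $d \approx 120$ nm, so a granule's
apparent brightness encodes its axial distance from the membrane. A
time-lapse TIRF movie therefore lets us ask, granule by granule: did it
arrive at the membrane (brightening), leave or fuse (dimming), or sit
docked (constant brightness)?

cgExoTrack implements the full desk-side analysis: spot detection,
particle linking, per-track feature extraction and classification, and
morphometry of the cortical actin clearances through which granules reach
the membrane. Because raw microscope data for this kind of experiment are
rarely shareable at useful scale, the package also contains a
ground-truthed simulator of both the movies and the actin images, and
every stage is validated against that ground truth.

## Spot detection

Detection uses a difference-of-Gaussians (DoG) filter matched to the
expected blob size. For an estimated blob diameter $D$ (default 0.6 µm,
appropriate for a sub-diffraction vesicle imaged at ~0.2 µm PSF width)
the inner scale is $\sigma_1 = (D/2)/\sqrt{2}$ and the outer scale
$\sigma_2 = 1.6\,\sigma_1$, the standard scale-space approximation to the
Laplacian of Gaussian. The response is rescaled so a unit-amplitude
Gaussian blob of the nominal diameter yields a peak response of 1, which
makes the *quality* of a detection (the response at its maximum) an
amplitude in image-intensity units. The default quality floor of 120
follows common TrackMate practice on EMCCD data; it is an
instrument-scaled number, so for differently scaled images you should
either set `qualityMin` yourself or use the Otsu auto-threshold
(`useAutoThreshold = TRUE`, `autoQualityThreshold()`), which separates
the spot-quality histogram into background responses and true spots.

Local maxima are kept with a minimum separation of one blob radius
(greedy non-maximum suppression in decreasing response order; ties broken
by raw intensity, then by lower (y, x)); positions are refined by a
quadratic fit of the 3×3 response neighborhood, with offsets clamped to
half a pixel. Spot intensity is the background-subtracted sum in a disk
of the blob radius, with background estimated as the median of a
1.5–2.5-radius annulus. On noiseless rendered movies the localization
error is below 0.1 px RMS; the half-pixel clamp bounds the worst case.

## Linking and gap closing

Tracks are built in the two-phase "simple LAP" fashion: frame-to-frame
linking, then gap closing, with no merging or splitting and no motion
model. For each consecutive frame pair a linear assignment problem is
solved with cost equal to squared distance for candidate pairs within the
linking radius (default 1.0 µm) and per-spot "no-link" alternatives
priced at $1.05\,d_{max}^2$, the conventional padding that still prefers
a near-threshold link over terminating a track. Gap closing solves one
further assignment between fragment ends and fragment starts, admissible
when the start follows the end by at most the maximum frame gap (default
2) within the gap-closing radius (default 1.0 µm).

Two conventions exist for "maximum frame gap = 2": bridged spots at most
2 frames apart (one missing frame), or up to 2 missing frames. We adopt
the first, and expose the second as
`linkingConfig(gapConvention = "missing_frames")`. The assignment
sub-solver is `clue::solve_LSAP`; the package's own tests verify both
phases against exhaustive minimum-cost matching for up to 5 spots per
frame.

## The track library

For every track the package computes per-timepoint values (step
displacement, cumulative displacement, percent-of-max intensity) and
per-track aggregates: duration, start/end time, net displacement, path
length, mean step speed, mean intensity, the minimum-area enclosing
ellipse (Khachiyan's algorithm, tolerance $10^{-7}$, with a final
minimal inflation so containment is exact; a 2σ covariance ellipse is
available via `ellipseMethod = "covariance"`), and the regression
aggregates on which classification rests.

**Profile classes.** The percent-of-max intensity series is regressed on
time by ordinary least squares (closed form, exact normal equations). A
track is *appearing* when $R^2 > 0.6$, $p < 0.05$ and the slope is
positive; *vanishing* with a negative slope; *neither* otherwise.
Normalizing each track to its own maximum makes the classes strictly
scale-invariant — multiplying a track's intensities by any positive
constant cannot change its class — which matters because absolute
brightness varies with axial position and expression level. Tracks with
fewer than 3 points, or with non-positive maximum intensity, are
*neither*: the classifier is total. $R^2$ for a zero-variance response is
defined as 0 for the same reason. With 30-point tracks, a ±1.5 %/frame
trend and 5 % Gaussian noise, recovery of appearing and vanishing tracks
exceeds 95 %, as does the specificity on flat tracks (the test suite
measures this).

**Duration classes.** Granule-track durations are empirically bimodal:
a peak of brief appearances (< 8 s) and a peak of tracks spanning the
whole movie. We therefore classify *long* = present at both the first
and last frame, *short* = duration under 8 s, *medium* = the rest, in
that precedence order, so the classes partition. Both the 8 s bound and
the full-span rule are configuration (`durationThresholds()`); the
duration histogram in the figure suite is the tool for re-deriving them
on new data.

**Stationary granules** are full-span tracks with a *neither* profile
and net displacement at most 0.5 µm (slightly less than one blob
diameter; configurable). The brightness criterion comes first — a
full-span appearing track is approaching, not docked.

**Group comparisons.** Two-sample comparisons use the unpaired two-tailed
Student's t-test (equal variances); percentage compositions use the
"N−1" chi-squared test, i.e. Pearson's statistic scaled by $(N-1)/N$,
referred to $\chi^2_{k-1}$ for a 2×k table — the recommended test for
comparing proportions at moderate counts.

## Cortical actin clearances

Granule fusion requires locally clearing the cortical actin mesh. On a
single actin-channel image the pipeline: (1) thresholds with the
percentile (Doyle) auto-threshold — on a 256-bin histogram the threshold
is placed where the cumulative pixel fraction is closest to 0.5, and with
"dark background" off the pixels *below* it (the actin-free regions) form
the mask; (2) labels connected components (8-connectivity by default);
(3) measures area (pixel count × pixel area) and perimeter (Moore
boundary trace, diagonal steps weighted $\sqrt{2}$, as ImageJ does) and
circularity $4\pi A/P^2$, clamped at 1; (4) keeps regions with area
1–40 µm² and circularity 0.2–1.0, discarding border-touching regions;
and (5) reports the clearance frequency per µm². On digital disks of
radius ≥ 10 px the circularity estimator lands in [0.85, 1.0]; the
analytic square value is exactly $\pi/4$.

Two further operations support the accompanying measurements:
`actinContact()` flags granules with any supra-threshold actin pixel
within 0.3 µm (our explicit operationalization of a contact count —
the radius equals the blob radius and the default threshold is the 75th
intensity percentile, both configurable, since no standard definition
exists), and `cortexVsCytoplasmIntensity()` splits a cell mask into a
1.0 µm cortical shell (the CG layer sits 0.4–0.6 µm inside the membrane)
and interior by erosion. `lineProfile()` gives width-averaged bilinear
profiles.

## The synthetic-data generator

`simulateTracks()` draws particle populations from five behavior classes.
Stationary particles jitter around a fixed point; diffusive steps are
isotropic Gaussian with variance $2D\Delta t$ per axis; directed motion
adds $v\Delta t$ along a per-particle fixed heading. Appearing and
vanishing particles move axially at a constant rate and their pre-noise
intensity follows the evanescent law $I_0 e^{-z(t)/d}$ with $d$ = 120 nm
by default — the simulator embodies the TIRF physics rather than an
arbitrary intensity ramp, so an appearing particle crossing from
$z = 240$ nm to the membrane brightens exactly $e^2 \approx 7.39$-fold. A
linear-ramp mode (`rampRate`) exists for classifier unit tests. Missed
detections are isolated single-frame events (a miss forces the next
frame visible), matching the dropout structure that gap closing at one
missing frame is designed to repair. Particles may leave the field of
view and are then flagged invisible, not reflected.

`renderMovie()` renders each particle as a pixel-integrated Gaussian (so
photometry is exact by construction), adds a constant background, then
Poisson shot noise followed by Gaussian read noise, clipping at zero.
Three optics presets reflect the imaging modalities the defaults were
chosen for: `"TIRFM"` (0.254 µm pixels, 10 s cadence, 31 frames),
`"iSIM"` (0.107 µm, 10 s) and `"iTIRF-SIM"` (0.0334 µm, 1 s, 50 frames).
Because no granule diffusion coefficients or speeds are established
numerically in the literature we model, motion parameters are free
simulation parameters with deliberately modest defaults (e.g.
$D \sim 10^{-3}$–$10^{-2}$ µm²/s), not empirical claims.

`simulateCortexImage()` builds an actin-cortex image as: a uniform
membrane background; sparse bright filaments (random blurred line
segments, default 8 filaments/µm² of ~0.08 µm width — a dense fine
mesh); dark elliptical clearances of known center, semi-axes and
orientation, each surrounded by a thin brighter rim of compacted actin
(as seen around clearance edges in vivo); a peripheral intensity falloff,
because the curved egg surface leaves the evanescent field away from the
central cortex patch; and pixel-scale Gaussian noise. The reported ground
truth is analytic: area $\pi ab$ and circularity from Ramanujan's
perimeter approximation. This design makes the percentile-threshold +
analyze-particles chain well-posed on synthetic data: the sub-threshold
half of the image is the peripheral ring (border-touching, filtered) plus
sub-resolution speckle, so detected clearances correspond one-to-one to
planted ones for areas within 2–30 µm². What the simulator does *not*
emulate: deconvolution artifacts, spatially varying background inside
the patch, filament bundling, or clearance shapes beyond smooth ellipses
— so passing recovery tests demonstrates correctness of the measurement
chain, not robustness to every real-data pathology.

## Numerical and design choices

- **Coordinates.** Pixel (r, c) has its center at
  ((c−0.5)·px, (r−0.5)·px) µm; all persisted positions are in µm. One
  convention, enforced in tests.
- **Determinism.** Every stochastic operation takes a seed;
  `runPipeline()` derives stage seeds from the master seed, and two runs
  with the same configuration produce byte-identical CSVs.
- **Assignment ties** are broken by the deterministic index order of the
  solver, so linking is reproducible.
- **16-bit TIFF storage** divides counts by 65535 with a JSON sidecar
  recording calibration and scale; integer stacks round-trip exactly.
- **Problem sizes in the test-suite** (movies of 48–256 px, 2–31 frames,
  ≤ 4000 particles; cortex images ≤ 448 px) were chosen as the smallest
  sizes at which the statistical assertions have comfortable power.

## Limitations

The tracker has no motion model and no merge/split handling, so crossing
granules within the linking radius can swap identities; in practice the
wide spacing of docked cortical granules makes this rare.
Quality thresholds are intensity-scale dependent. The clearance analysis
is single-frame; temporal clearance tracking is out of scope, as are 3D
reconstruction, deconvolution and kymographs.
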