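# cgExoTrack

Single-granule analysis of cortical granule exocytosis in TIRF
time-lapse movies, for cell biologists quantifying regulated secretion
in mouse eggs (or any system where sub-diffraction vesicles dock at and
fuse with the plasma membrane under evanescent-field illumination).

Cortical granules (~200 nm vesicles) sit in a layer just beneath the egg
plasma membrane and are released after fertilization to block polyspermy.
In TIRF microscopy the excitation intensity decays as `exp(-z/d)` with a
penetration depth `d ≈ 120 nm`, so a granule's brightness reports its
axial distance from the membrane. The package turns raw 2D+t movies into
per-granule answers — *arriving*, *leaving/fusing*, or *docked* — and
quantifies the actin-free cortical clearances through which granules
reach the membrane:

- **Detection** — difference-of-Gaussians filter at blob diameter 0.6 µm
  (`σ₁ = r/√2`, `σ₂ = 1.6 σ₁`), quality threshold 120 (or Otsu
  auto-threshold), sub-pixel localization by quadratic fit.
- **Tracking** — two-phase "simple LAP" linking: frame-to-frame
  assignment with squared-distance costs within 1.0 µm, no-link
  alternatives at `1.05·d²max`, then gap closing across at most a
  2-frame gap within 1.0 µm.
- **Track library** — percent-of-max intensity per timepoint; per-track
  OLS regression of percent-of-max on time. A track is **appearing** if
  `R² > 0.6`, `p < 0.05` and slope > 0; **vanishing** with slope < 0;
  **neither** otherwise. Duration classes: **long** = spans the movie,
  **short** = under 8 s, **medium** = between. Stationary = full-span,
  flat profile, net displacement ≤ 0.5 µm. Minimum enclosing ellipses,
  displacement and speed aggregates; Student's t and N−1 chi-squared
  group comparisons.
- **Cortex analysis** — percentile ("dark background" off) threshold,
  connected components, area 1–40 µm² and circularity 0.2–1.0 filters,
  clearance frequency per µm², granule–actin contact flags,
  cortex-vs-cytoplasm intensity, line profiles.
- **Synthetic data** — a ground-truthed generator for TIRF movies
  (stationary/diffusive/directed/appearing/vanishing granules rendered
  as pixel-integrated Gaussians with Poisson + read noise, intensity
  driven by the evanescent law) and actin-cortex images with planted
  elliptical clearances of analytically known area and circularity.
  Every pipeline stage is validated against this ground truth.

TrackMate XML import, multi-page TIFF I/O with JSON calibration
sidecars, CSV tables, YAML pipeline configs, and a five-panel figure
suite are included. See the vignette (`vignettes/granule-tracking.Rmd`)
for the methods in detail.

## Worked example

Simulate a 5-minute TIRF experiment (0.254 µm pixels, one frame per
10 s) containing docked, arriving and departing granules, then run the
analysis:

```r
library(cgExoTrack)

optics <- opticsPreset("TIRFM")
behaviors <- list(
  behaviorSpec("stationary", 5, jitterSdUm = 0.01),
  behaviorSpec("appearing",  4, zStartUm = 0.30, zRateUmS = 0.001),
  behaviorSpec("vanishing",  4, zStartUm = 0,    zRateUmS = 0.001))
truth <- simulateTracks(behaviors, optics, seed = 7)
movie <- renderMovie(truth, optics, seed = 8)
movie
#> TirfMovie: 96 x 96 px, 31 frames, 0.254 um/px, 10 s/frame

spots  <- detectSpots(movie, detectionConfig())   # DoG 0.6 um, quality 120
tracks <- trackSpots(spots, linkingConfig())      # LAP 1.0 um, frame gap 2
tracks
#> TrackSet: 14 tracks, 364 spots, 0 closed gaps

feats <- trackFeatures(tracks, movieSpan = c(1L, nFrames(movie)),
                       intervalS = frameInterval(movie))
table(feats$profile_class)
#> appearing   neither vanishing
#>         4         6         4
sum(feats$stationary)
#> [1] 5
```

All 4 simulated arriving granules and all 4 departing ones are recovered
(the appearing ones brightened `e^2.5 ≈ 12`-fold while moving 0.30 µm
toward the membrane), and the 5 docked granules are flagged stationary.
The appearing tracks' regression aggregates:

```r
subset(feats, profile_class == "appearing",
       select = c(track_id, duration_s, slope_pct_per_s, r2, p_value))
#>    track_id duration_s slope_pct_per_s    r2  p_value
#> 10       10        270           0.317 0.917 1.55e-15
#> 12       12        250           0.323 0.926 4.41e-15
#> 13       13        240           0.353 0.936 3.42e-15
#> 14       14        230           0.367 0.941 4.91e-15
```

Clearance morphometry on a simulated actin cortex:

```r
sim   <- simulateCortexImage(cortexSimSpec(imageSizePx = c(448L, 448L),
                                           nClearances = 6L, seed = 9))
mask  <- percentileThreshold(sim$image)
clear <- findClearances(mask, sim$pixelSizeUm, clearanceConfig())
round(sort(clear$area_um2), 2)
#> [1]  5.68  7.20 13.61 14.06 16.27 18.07   # true: 5.64 7.21 13.68 14.06 16.29 18.12
round(clearanceFrequency(clear, prod(dim(sim$image)) * sim$pixelSizeUm^2), 4)
#> [1] 0.0026
```

All six planted clearances are found, with areas within ~0.5 % of the
analytic truth; the frequency is per µm² of analyzed cortex.

`runPipeline("inst/extdata/demo-config.yaml")` composes the whole chain —
simulate, render, detect, track, classify, clearance analysis, figures,
manifest — deterministically from one seed. A thin command-line wrapper
(`inst/cli/cg-pipeline.R`) exposes `simulate`, `detect`, `track`,
`classify`, `clearance`, `import-trackmate` and `run-all` subcommands.

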