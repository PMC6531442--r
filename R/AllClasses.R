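#' @import methods
NULL

## ---------------------------------------------------------------------------
## Optics / acquisition geometry
## ---------------------------------------------------------------------------

#' Optical and acquisition configuration
#'
#' Describes the imaging geometry and camera model used both to render
#' synthetic movies and to calibrate analysis: pixel size, frame interval,
#' stack size, PSF width, background and noise levels, and the evanescent
#' penetration depth of the TIRF field that couples a particle's axial
#' position to its apparent brightness.
#'
#' @slot pixelSizeUm lateral pixel size in micrometers.
#' @slot frameIntervalS time between frames in seconds.
#' @slot nFrames number of frames in the stack.
#' @slot fovPx integer vector (height, width) of the field of view in pixels.
#' @slot psfSigmaUm Gaussian PSF standard deviation in micrometers.
#' @slot backgroundLevel mean background in photons per pixel.
#' @slot photonScale photons emitted per unit model intensity.
#' @slot readNoiseSd Gaussian read noise standard deviation in photons.
#' @slot penetrationDepthUm evanescent-field 1/e penetration depth (um).
#'
#' @seealso [opticsConfig()], [opticsPreset()]
#' @exportClass OpticsConfig
setClass("OpticsConfig",
  representation(
    pixelSizeUm        = "numeric",
    frameIntervalS     = "numeric",
    nFrames            = "integer",
    fovPx              = "integer",
    psfSigmaUm         = "numeric",
    backgroundLevel    = "numeric",
    photonScale        = "numeric",
    readNoiseSd        = "numeric",
    penetrationDepthUm = "numeric"
  )
)

setValidity("OpticsConfig", function(object) {
  msg <- character()
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be > 0")
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  if (length(object@fovPx) != 2L || any(object@fovPx < 8L))
    msg <- c(msg, "fovPx must be (height, width), each >= 8 px")
  if (object@psfSigmaUm < object@pixelSizeUm / 4)
    msg <- c(msg, "psfSigmaUm must be >= pixelSizeUm/4 (renderable PSF)")
  if (object@penetrationDepthUm <= 0) msg <- c(msg, "penetrationDepthUm must be > 0")
  if (object@backgroundLevel < 0 || object@photonScale <= 0 || object@readNoiseSd < 0)
    msg <- c(msg, "backgroundLevel/readNoiseSd must be >= 0 and photonScale > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an OpticsConfig
#'
#' @param pixelSizeUm lateral pixel size (um). Default 0.107 (iSIM 60x).
#' @param frameIntervalS frame interval (s).
#' @param nFrames frames in the stack.
#' @param fovPx integer (height, width) in pixels.
#' @param psfSigmaUm Gaussian PSF sigma (um). The default 0.21 corresponds
#'   to a ~0.6 um effective blob diameter for a sub-diffraction granule
#'   (blob radius = sigma * sqrt(2)).
#' @param backgroundLevel mean background photons per pixel.
#' @param photonScale photons per unit model intensity.
#' @param readNoiseSd camera read noise sd (photons).
#' @param penetrationDepthUm evanescent 1/e depth (um), default 0.120.
#' @return an [OpticsConfig-class] object.
#' @examples
#' opticsConfig(nFrames = 10L, fovPx = c(64L, 64L))
#' @export
opticsConfig <- function(pixelSizeUm = 0.107, frameIntervalS = 10,
                         nFrames = 31L, fovPx = c(128L, 128L),
                         psfSigmaUm = 0.21, backgroundLevel = 100,
                         photonScale = 5000, readNoiseSd = 3,
                         penetrationDepthUm = 0.120) {
  new("OpticsConfig",
      pixelSizeUm = pixelSizeUm, frameIntervalS = frameIntervalS,
      nFrames = as.integer(nFrames), fovPx = as.integer(fovPx),
      psfSigmaUm = psfSigmaUm, backgroundLevel = backgroundLevel,
      photonScale = photonScale, readNoiseSd = readNoiseSd,
      penetrationDepthUm = penetrationDepthUm)
}

#' Named optics presets for the three imaging modalities
#'
#' `"TIRFM"`: diffraction-limited TIRF, 0.254 um pixels, 10 s cadence,
#' 31 frames (5 min). `"iSIM"`: 0.107 um pixels, 10 s cadence.
#' `"iTIRF-SIM"`: instant TIRF-SIM, 0.0334 um pixels, 1 s cadence,
#' 50 frames. Fields not fixed by the modality (field of view, noise)
#' take generator defaults and can be overridden via `...`.
#'
#' @param name one of `"TIRFM"`, `"iSIM"`, `"iTIRF-SIM"`.
#' @param ... overrides passed to [opticsConfig()].
#' @return an [OpticsConfig-class].
#' @examples
#' opticsPreset("TIRFM")
#' @export
opticsPreset <- function(name = c("TIRFM", "iSIM", "iTIRF-SIM"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "TIRFM"     = list(pixelSizeUm = 0.254,  frameIntervalS = 10, nFrames = 31L,
                       fovPx = c(96L, 96L)),
    "iSIM"      = list(pixelSizeUm = 0.107,  frameIntervalS = 10, nFrames = 31L,
                       fovPx = c(192L, 192L)),
    "iTIRF-SIM" = list(pixelSizeUm = 0.0334, frameIntervalS = 1,  nFrames = 50L,
                       fovPx = c(256L, 256L))
  )
  over <- list(...)
  do.call(opticsConfig, utils::modifyList(base, over))
}

## ---------------------------------------------------------------------------
## Behavior specification for simulated granules
## ---------------------------------------------------------------------------

#' Behavior specification for simulated granules
#'
#' One population of simulated particles sharing a motion/intensity model.
#' Labels: `stationary` (fixed position plus jitter, constant intensity),
#' `diffusive` (2D Brownian motion), `directed` (constant velocity along a
#' random fixed heading plus diffusion), `appearing` (axial approach to the
#' membrane through the evanescent field, rising intensity) and `vanishing`
#' (axial retreat, decaying intensity).
#'
#' @slot label behavior class.
#' @slot nParticles particles in this population.
#' @slot diffusionCoeffUm2S diffusion coefficient D (um^2/s).
#' @slot speedUmS directed speed (um/s).
#' @slot jitterSdUm per-frame positional jitter sd (um).
#' @slot zStartUm initial axial distance from the coverslip focal plane (um).
#' @slot zRateUmS axial speed (um/s); appearing particles move toward z = 0,
#'   vanishing away from it.
#' @slot birthFrameRange inclusive (lo, hi) range of the first frame.
#' @slot deathFrameRange inclusive (lo, hi) range of the last frame.
#' @slot intensity baseline model intensity I0 at z = 0.
#' @slot rampRate optional linear intensity ramp (fraction of I0 per second);
#'   when nonzero it replaces the evanescent exponential (diagnostic mode).
#' @slot missProb probability that a frame's detection is missed.
#' @exportClass BehaviorSpec
setClass("BehaviorSpec",
  representation(
    label = "character", nParticles = "integer",
    diffusionCoeffUm2S = "numeric", speedUmS = "numeric",
    jitterSdUm = "numeric", zStartUm = "numeric", zRateUmS = "numeric",
    birthFrameRange = "integer", deathFrameRange = "integer",
    intensity = "numeric", rampRate = "numeric", missProb = "numeric"
  )
)

.behaviorLabels <- c("stationary", "diffusive", "directed", "appearing", "vanishing")

setValidity("BehaviorSpec", function(object) {
  msg <- character()
  if (!object@label %in% .behaviorLabels)
    msg <- c(msg, paste("label must be one of:", paste(.behaviorLabels, collapse = ", ")))
  if (object@nParticles < 1L) msg <- c(msg, "nParticles must be >= 1")
  if (object@missProb < 0 || object@missProb > 1) msg <- c(msg, "missProb must be in [0, 1]")
  if (object@diffusionCoeffUm2S < 0 || object@speedUmS < 0 || object@jitterSdUm < 0 ||
      object@zRateUmS < 0)
    msg <- c(msg, "rates must be >= 0")
  if (object@zStartUm < 0) msg <- c(msg, "zStartUm must be >= 0")
  if (length(object@birthFrameRange) != 2L || length(object@deathFrameRange) != 2L)
    msg <- c(msg, "birth/death frame ranges must have length 2")
  if (length(msg)) msg else TRUE
})

#' Construct a BehaviorSpec
#'
#' @param label one of `"stationary"`, `"diffusive"`, `"directed"`,
#'   `"appearing"`, `"vanishing"`.
#' @param nParticles number of particles.
#' @param diffusionCoeffUm2S diffusion coefficient (um^2/s).
#' @param speedUmS directed speed (um/s).
#' @param jitterSdUm positional jitter sd per frame (um).
#' @param zStartUm starting axial depth (um); used by appearing/vanishing.
#' @param zRateUmS axial speed (um/s); used by appearing/vanishing.
#' @param birthFrame first frame, scalar or (lo, hi) sampled uniformly.
#' @param deathFrame last frame, scalar or (lo, hi); `NA` means last frame
#'   of the movie.
#' @param intensity baseline model intensity at the coverslip.
#' @param rampRate linear intensity ramp per second (diagnostic alternative
#'   to the evanescent model; 0 disables).
#' @param missProb per-frame missed-detection probability. Misses are
#'   isolated: a missed frame is always followed by a visible one.
#' @return a [BehaviorSpec-class].
#' @examples
#' behaviorSpec("diffusive", 10, diffusionCoeffUm2S = 0.01)
#' @export
behaviorSpec <- function(label, nParticles,
                         diffusionCoeffUm2S = 0, speedUmS = 0, jitterSdUm = 0,
                         zStartUm = 0, zRateUmS = 0,
                         birthFrame = 1L, deathFrame = NA,
                         intensity = 1, rampRate = 0, missProb = 0) {
  rng <- function(x) {
    x <- as.integer(x)
    if (length(x) == 1L) c(x, x) else x
  }
  if (length(deathFrame) == 1L && is.na(deathFrame)) deathFrame <- c(-1L, -1L)
  new("BehaviorSpec",
      label = label, nParticles = as.integer(nParticles),
      diffusionCoeffUm2S = diffusionCoeffUm2S, speedUmS = speedUmS,
      jitterSdUm = jitterSdUm, zStartUm = zStartUm, zRateUmS = zRateUmS,
      birthFrameRange = rng(birthFrame), deathFrameRange = rng(deathFrame),
      intensity = intensity, rampRate = rampRate, missProb = missProb)
}

## ---------------------------------------------------------------------------
## Ground truth
## ---------------------------------------------------------------------------

#' Simulated ground truth
#'
#' Per-particle, per-frame true state of a simulated movie: position,
#' axial depth, pre-noise model intensity, behavior label and visibility.
#' `inFov` records whether the particle lies inside the field of view;
#' `visible` additionally accounts for missed detections, so it is the
#' flag a perfect detector would reproduce.
#'
#' @slot data data.frame with columns `particle_id`, `label`, `frame`,
#'   `t_s`, `x_um`, `y_um`, `z_um`, `intensity`, `in_fov`, `visible`.
#' @slot optics the [OpticsConfig-class] used for simulation.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(data = "data.frame", optics = "OpticsConfig"))

setValidity("GroundTruth", function(object) {
  need <- c("particle_id", "label", "frame", "t_s", "x_um", "y_um", "z_um",
            "intensity", "in_fov", "visible")
  msg <- character()
  if (!all(need %in% names(object@data)))
    msg <- c(msg, paste("missing columns:", paste(setdiff(need, names(object@data)), collapse = ", ")))
  else if (nrow(object@data) && any(object@data$intensity < 0))
    msg <- c(msg, "intensity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn GroundTruth-class the ground-truth table.
#' @param x a `GroundTruth`.
#' @export
truthTable <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@data
}

#' @describeIn GroundTruth-class the optics used for simulation.
#' @export
truthOptics <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@optics
}

setMethod("show", "GroundTruth", function(object) {
  d <- object@data
  cat("GroundTruth:", length(unique(d$particle_id)), "particles,",
      if (nrow(d)) max(d$frame) else 0L, "frames\n")
  if (nrow(d)) {
    tab <- table(d$label[!duplicated(d$particle_id)])
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

## ---------------------------------------------------------------------------
## Movie container
## ---------------------------------------------------------------------------

#' Calibrated time-lapse movie
#'
#' A 2D+t fluorescence stack with physical calibration. Pixel values are
#' photon-like counts; `frames(x)[, , k]` is frame `k` with rows indexing
#' y and columns indexing x. The pixel-center convention maps column `c`
#' to x = (c - 0.5) * pixelSize and row `r` to y = (r - 0.5) * pixelSize.
#'
#' @slot data numeric array (height, width, frames).
#' @slot pixelSizeUm pixel size (um).
#' @slot frameIntervalS frame interval (s).
#' @exportClass TirfMovie
setClass("TirfMovie",
  representation(data = "array", pixelSizeUm = "numeric", frameIntervalS = "numeric"))

setValidity("TirfMovie", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3D array (h, w, t)")
  if (object@pixelSizeUm <= 0 || object@frameIntervalS <= 0)
    msg <- c(msg, "calibration must be positive")
  if (anyNA(object@data)) msg <- c(msg, "movie contains NA values")
  if (length(msg)) msg else TRUE
})

#' Construct a TirfMovie
#' @param data array (height, width, frames).
#' @param pixelSizeUm pixel size (um).
#' @param frameIntervalS frame interval (s).
#' @return a [TirfMovie-class].
#' @export
tirfMovie <- function(data, pixelSizeUm, frameIntervalS) {
  new("TirfMovie", data = data, pixelSizeUm = pixelSizeUm,
      frameIntervalS = frameIntervalS)
}

#' @describeIn TirfMovie-class the raw stack array (h, w, t).
#' @param x a `TirfMovie`.
#' @export
frames <- function(x) {
  stopifnot(is(x, "TirfMovie"))
  x@data
}

#' @describeIn TirfMovie-class number of frames.
#' @export
nFrames <- function(x) {
  stopifnot(is(x, "TirfMovie"))
  dim(x@data)[3L]
}

#' @describeIn TirfMovie-class pixel size in micrometers.
#' @export
pixelSize <- function(x) {
  if (is(x, "TirfMovie") || is(x, "OpticsConfig")) x@pixelSizeUm
  else stop("pixelSize() needs a TirfMovie or OpticsConfig")
}

#' @describeIn TirfMovie-class frame interval in seconds.
#' @export
frameInterval <- function(x) {
  if (is(x, "TirfMovie") || is(x, "OpticsConfig")) x@frameIntervalS
  else stop("frameInterval() needs a TirfMovie or OpticsConfig")
}

setMethod("show", "TirfMovie", function(object) {
  d <- dim(object@data)
  cat(sprintf("TirfMovie: %d x %d px, %d frames, %.4g um/px, %.4g s/frame\n",
              d[1], d[2], d[3], object@pixelSizeUm, object@frameIntervalS))
})

## ---------------------------------------------------------------------------
## Analysis configuration classes
## ---------------------------------------------------------------------------

#' Spot-detection configuration
#'
#' Difference-of-Gaussians detector settings. The defaults mirror common
#' TrackMate practice for ~200 nm granules: estimated blob diameter 0.6 um
#' and an initial quality threshold of 120. The quality value is a detector
#' response in image-intensity units: it is only meaningful for images
#' scaled comparably to the instrument it was chosen on, so for synthetic
#' or re-scaled data either set `qualityMin` explicitly or enable
#' `useAutoThreshold` (Otsu on the quality histogram).
#'
#' @slot blobDiameterUm estimated blob diameter (um), default 0.6.
#' @slot qualityMin initial quality threshold, default 120.
#' @slot useAutoThreshold apply [autoQualityThreshold()] after the initial cut.
#' @slot dogSigmaRatio ratio of the two DoG sigmas, default 1.6.
#' @slot subpixel quadratic sub-pixel refinement flag.
#' @exportClass DetectionConfig
setClass("DetectionConfig",
  representation(blobDiameterUm = "numeric", qualityMin = "numeric",
                 useAutoThreshold = "logical", dogSigmaRatio = "numeric",
                 subpixel = "logical"))

setValidity("DetectionConfig", function(object) {
  msg <- character()
  if (object@blobDiameterUm <= 0) msg <- c(msg, "blobDiameterUm must be > 0")
  if (object@qualityMin < 0) msg <- c(msg, "qualityMin must be >= 0")
  if (object@dogSigmaRatio <= 1) msg <- c(msg, "dogSigmaRatio must be > 1")
  if (length(msg)) msg else TRUE
})

#' @rdname DetectionConfig-class
#' @param blobDiameterUm,qualityMin,useAutoThreshold,dogSigmaRatio,subpixel
#'   see slot documentation.
#' @return a `DetectionConfig`.
#' @export
detectionConfig <- function(blobDiameterUm = 0.6, qualityMin = 120,
                            useAutoThreshold = FALSE, dogSigmaRatio = 1.6,
                            subpixel = TRUE) {
  new("DetectionConfig", blobDiameterUm = blobDiameterUm, qualityMin = qualityMin,
      useAutoThreshold = useAutoThreshold, dogSigmaRatio = dogSigmaRatio,
      subpixel = subpixel)
}

#' Particle-linking configuration
#'
#' Two-phase LAP linking settings: frame-to-frame linking distance,
#' gap-closing distance, maximum frame gap and the alternative (no-link)
#' cost factor. The default 1.0 um distances and frame gap 2 follow the
#' simple LAP tracker settings used for cortical granules. `gapConvention`
#' selects how the frame gap is counted: `"frame_difference"` (bridged
#' spots at most `maxFrameGap` frames apart, i.e. at most one missing
#' frame at the default) or `"missing_frames"` (up to `maxFrameGap`
#' undetected frames between them).
#'
#' @slot maxLinkDistUm frame-to-frame linking radius (um).
#' @slot maxGapDistUm gap-closing radius (um).
#' @slot maxFrameGap maximum frame gap (see `gapConvention`).
#' @slot alternativeCostFactor no-link cost = factor * dist^2.
#' @slot gapConvention `"frame_difference"` or `"missing_frames"`.
#' @exportClass LinkingConfig
setClass("LinkingConfig",
  representation(maxLinkDistUm = "numeric", maxGapDistUm = "numeric",
                 maxFrameGap = "integer", alternativeCostFactor = "numeric",
                 gapConvention = "character"))

setValidity("LinkingConfig", function(object) {
  msg <- character()
  if (object@maxLinkDistUm <= 0 || object@maxGapDistUm <= 0)
    msg <- c(msg, "linking distances must be > 0")
  if (object@maxFrameGap < 0L) msg <- c(msg, "maxFrameGap must be >= 0")
  if (object@alternativeCostFactor <= 1)
    msg <- c(msg, "alternativeCostFactor must be > 1")
  if (!object@gapConvention %in% c("frame_difference", "missing_frames"))
    msg <- c(msg, "gapConvention must be 'frame_difference' or 'missing_frames'")
  if (length(msg)) msg else TRUE
})

#' @rdname LinkingConfig-class
#' @param maxLinkDistUm,maxGapDistUm,maxFrameGap,alternativeCostFactor,gapConvention
#'   see slot documentation.
#' @return a `LinkingConfig`.
#' @export
linkingConfig <- function(maxLinkDistUm = 1.0, maxGapDistUm = 1.0,
                          maxFrameGap = 2L, alternativeCostFactor = 1.05,
                          gapConvention = "frame_difference") {
  new("LinkingConfig", maxLinkDistUm = maxLinkDistUm, maxGapDistUm = maxGapDistUm,
      maxFrameGap = as.integer(maxFrameGap),
      alternativeCostFactor = alternativeCostFactor,
      gapConvention = gapConvention)
}

#' Intensity-profile classification criteria
#'
#' A track is called `appearing` when the linear regression of its
#' percent-of-max intensity on time has R^2 > `r2Min`, p < `pMax` and a
#' positive slope; `vanishing` with a negative slope; `neither` otherwise.
#' Tracks shorter than `minPoints` detections are `neither`.
#'
#' @slot r2Min minimum R^2 (default 0.6).
#' @slot pMax maximum regression p-value (default 0.05).
#' @slot minPoints minimum detections for a defined regression (default 3).
#' @exportClass ProfileCriteria
setClass("ProfileCriteria",
  representation(r2Min = "numeric", pMax = "numeric", minPoints = "integer"))

setValidity("ProfileCriteria", function(object) {
  msg <- character()
  if (object@r2Min < 0 || object@r2Min > 1) msg <- c(msg, "r2Min must be in [0, 1]")
  if (object@pMax <= 0 || object@pMax >= 1) msg <- c(msg, "pMax must be in (0, 1)")
  if (object@minPoints < 3L) msg <- c(msg, "minPoints must be >= 3")
  if (length(msg)) msg else TRUE
})

#' @rdname ProfileCriteria-class
#' @param r2Min,pMax,minPoints see slot documentation.
#' @return a `ProfileCriteria`.
#' @export
profileCriteria <- function(r2Min = 0.6, pMax = 0.05, minPoints = 3L) {
  new("ProfileCriteria", r2Min = r2Min, pMax = pMax, minPoints = as.integer(minPoints))
}

#' Track-duration class thresholds
#'
#' Duration classes follow the empirical bimodal distribution of granule
#' track durations: `long` tracks span the whole movie (present at the
#' first and last frame) when `longRule` is on, `short` tracks last less
#' than `shortMaxS` seconds (default 8 s), everything else is `medium`.
#'
#' @slot shortMaxS upper duration bound for short tracks (s).
#' @slot longRule when TRUE, long = present at both the first and last
#'   frame of the movie; when FALSE, long = duration equals the full span.
#' @exportClass DurationThresholds
setClass("DurationThresholds",
  representation(shortMaxS = "numeric", longRule = "logical"))

setValidity("DurationThresholds", function(object) {
  if (object@shortMaxS <= 0) "shortMaxS must be > 0" else TRUE
})

#' @rdname DurationThresholds-class
#' @param shortMaxS,longRule see slot documentation.
#' @return a `DurationThresholds`.
#' @export
durationThresholds <- function(shortMaxS = 8, longRule = TRUE) {
  new("DurationThresholds", shortMaxS = shortMaxS, longRule = longRule)
}

#' Actin-clearance detection configuration
#'
#' Filters applied to connected dark regions of a thresholded cortex
#' image, mirroring an analyze-particles run: area 1-40 um^2, circularity
#' 0.2-1.00, 8-connectivity, border-touching regions excluded.
#'
#' @slot areaMinUm2,areaMaxUm2 area bounds (um^2).
#' @slot circMin,circMax circularity bounds (4*pi*A/P^2).
#' @slot connectivity 4 or 8.
#' @slot excludeBorder drop regions touching the image border.
#' @exportClass ClearanceConfig
setClass("ClearanceConfig",
  representation(areaMinUm2 = "numeric", areaMaxUm2 = "numeric",
                 circMin = "numeric", circMax = "numeric",
                 connectivity = "integer", excludeBorder = "logical"))

setValidity("ClearanceConfig", function(object) {
  msg <- character()
  if (object@areaMinUm2 <= 0 || object@areaMinUm2 >= object@areaMaxUm2)
    msg <- c(msg, "need 0 < areaMinUm2 < areaMaxUm2")
  if (object@circMin < 0 || object@circMin > object@circMax || object@circMax > 1)
    msg <- c(msg, "need 0 <= circMin <= circMax <= 1")
  if (!object@connectivity %in% c(4L, 8L)) msg <- c(msg, "connectivity must be 4 or 8")
  if (length(msg)) msg else TRUE
})

#' @rdname ClearanceConfig-class
#' @param areaMinUm2,areaMaxUm2,circMin,circMax,connectivity,excludeBorder
#'   see slot documentation.
#' @return a `ClearanceConfig`.
#' @export
clearanceConfig <- function(areaMinUm2 = 1, areaMaxUm2 = 40,
                            circMin = 0.2, circMax = 1.0,
                            connectivity = 8L, excludeBorder = TRUE) {
  new("ClearanceConfig", areaMinUm2 = areaMinUm2, areaMaxUm2 = areaMaxUm2,
      circMin = circMin, circMax = circMax,
      connectivity = as.integer(connectivity), excludeBorder = excludeBorder)
}

## ---------------------------------------------------------------------------
## Track set
## ---------------------------------------------------------------------------

#' A set of linked particle tracks
#'
#' Result of two-phase LAP linking: a spot table with a `track_id` column
#' (frame-ordered within track) and a table of closed gaps (bridges made
#' during gap closing).
#'
#' @slot spots data.frame of spots with `track_id`.
#' @slot gaps data.frame with `track_id`, `frame_before`, `frame_after`.
#' @slot config the [LinkingConfig-class] used.
#' @exportClass TrackSet
setClass("TrackSet",
  representation(spots = "data.frame", gaps = "data.frame", config = "LinkingConfig"))

setValidity("TrackSet", function(object) {
  if (nrow(object@spots) && !all(c("track_id", "id", "frame", "x_um", "y_um") %in%
                                 names(object@spots)))
    "spots must have track_id, id, frame, x_um, y_um"
  else TRUE
})

#' @describeIn TrackSet-class the spot table with track assignments.
#' @param x a `TrackSet`.
#' @export
trackTable <- function(x) {
  stopifnot(is(x, "TrackSet"))
  x@spots
}

#' @describeIn TrackSet-class the closed-gap table.
#' @export
gapTable <- function(x) {
  stopifnot(is(x, "TrackSet"))
  x@gaps
}

#' @describeIn TrackSet-class number of tracks.
#' @export
nTracks <- function(x) {
  stopifnot(is(x, "TrackSet"))
  length(unique(x@spots$track_id))
}

setMethod("show", "TrackSet", function(object) {
  cat("TrackSet:", nTracks(object), "tracks,", nrow(object@spots), "spots,",
      nrow(object@gaps), "closed gaps\n")
})
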