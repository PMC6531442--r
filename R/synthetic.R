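## Ground-truthed synthetic TIRF data: vesicle trajectories, rendered
## movies and actin-cortex images with planted clearances.

#' Simulate granule trajectories with ground truth
#'
#' Generates per-frame true positions and pre-noise model intensities for
#' one or more behavior populations. Appearing and vanishing particles
#' move axially through the evanescent field, so their intensity follows
#' I(t) = I0 * exp(-z(t) / penetrationDepth) with z(t) linear in time
#' (decreasing toward the coverslip for appearing, increasing for
#' vanishing); when a spec sets a nonzero `rampRate` the exponential is
#' replaced by a linear ramp I0 * (1 + rampRate * (t - t_birth)).
#' Diffusive steps are isotropic Gaussian with variance 2 * D * dt per
#' axis; directed motion adds speed * dt along a per-particle fixed
#' heading. Particles leaving the field of view are flagged not-in-FOV
#' rather than reflected. Missed detections (`missProb`) are isolated
#' single-frame events: a miss is never followed by another miss.
#'
#' @param behaviors list of [BehaviorSpec-class] (a single spec is accepted).
#' @param optics an [OpticsConfig-class].
#' @param seed integer seed; identical seeds give identical output.
#' @return a [GroundTruth-class].
#' @examples
#' gt <- simulateTracks(behaviorSpec("stationary", 3),
#'                      opticsConfig(nFrames = 5L, fovPx = c(32L, 32L)), seed = 1)
#' head(truthTable(gt))
#' @export
simulateTracks <- function(behaviors, optics, seed = 1L) {
  if (is(behaviors, "BehaviorSpec")) behaviors <- list(behaviors)
  if (!length(behaviors)) stop("at least one BehaviorSpec is required")
  lapply(behaviors, function(b) stopifnot(is(b, "BehaviorSpec")))
  validObject(optics)
  if (optics@frameIntervalS <= 0) stop("frame interval must be positive")

  set.seed(as.integer(seed))
  dt <- optics@frameIntervalS
  nfr <- optics@nFrames
  h_um <- optics@fovPx[1] * optics@pixelSizeUm
  w_um <- optics@fovPx[2] * optics@pixelSizeUm
  margin <- min(1, 0.25 * min(h_um, w_um))  # keep starts away from the edge

  rows <- list()
  pid <- 0L
  for (b in behaviors) {
    for (k in seq_len(b@nParticles)) {
      pid <- pid + 1L
      birth <- .sampleFrame(b@birthFrameRange, nfr, 1L)
      death <- .sampleFrame(b@deathFrameRange, nfr, nfr)
      if (death < birth) death <- birth
      fr <- birth:death
      nf <- length(fr)
      t_rel <- (fr - birth) * dt

      x0 <- stats::runif(1, margin, w_um - margin)
      y0 <- stats::runif(1, margin, h_um - margin)
      theta <- stats::runif(1, 0, 2 * pi)

      x <- rep(x0, nf); y <- rep(y0, nf)
      if (b@diffusionCoeffUm2S > 0 && nf > 1) {
        sd_step <- sqrt(2 * b@diffusionCoeffUm2S * dt)
        x <- x0 + c(0, cumsum(stats::rnorm(nf - 1, 0, sd_step)))
        y <- y0 + c(0, cumsum(stats::rnorm(nf - 1, 0, sd_step)))
      }
      if (b@speedUmS > 0) {
        x <- x + b@speedUmS * t_rel * cos(theta)
        y <- y + b@speedUmS * t_rel * sin(theta)
      }
      if (b@jitterSdUm > 0) {
        x <- x + stats::rnorm(nf, 0, b@jitterSdUm)
        y <- y + stats::rnorm(nf, 0, b@jitterSdUm)
      }

      z <- rep(0, nf)
      if (b@label == "appearing") z <- pmax(0, b@zStartUm - b@zRateUmS * t_rel)
      if (b@label == "vanishing") z <- b@zStartUm + b@zRateUmS * t_rel
      inten <- if (b@rampRate != 0)
        pmax(0, b@intensity * (1 + b@rampRate * t_rel))
      else
        b@intensity * exp(-z / optics@penetrationDepthUm)

      in_fov <- x >= 0 & x <= w_um & y >= 0 & y <= h_um
      missed <- rep(FALSE, nf)
      if (b@missProb > 0) {
        u <- stats::runif(nf)
        for (i in seq_len(nf)) {
          if (u[i] < b@missProb && (i == 1L || !missed[i - 1L])) missed[i] <- TRUE
        }
      }

      rows[[pid]] <- data.frame(
        particle_id = pid, label = b@label, frame = fr, t_s = (fr - 1L) * dt,
        x_um = x, y_um = y, z_um = z, intensity = inten,
        in_fov = in_fov, visible = in_fov & !missed)
    }
  }
  new("GroundTruth", data = do.call(rbind, rows), optics = optics)
}

.sampleFrame <- function(rng, nfr, default) {
  if (rng[1] < 0L) return(as.integer(default))
  lo <- max(1L, min(rng[1], nfr)); hi <- max(1L, min(rng[2], nfr))
  if (hi <= lo) lo else as.integer(sample(lo:hi, 1L))
}

#' Convert ground truth to a spot table
#'
#' Produces the table an ideal detector would return: one row per visible
#' ground-truth entry, with unique spot ids. Useful for testing the
#' linker in isolation from the detector.
#'
#' @param truth a [GroundTruth-class].
#' @return data.frame with `id`, `frame`, `t_s`, `x_um`, `y_um`,
#'   `quality`, `intensity`.
#' @export
truthToSpots <- function(truth) {
  d <- truthTable(truth)
  d <- d[d$visible, , drop = FALSE]
  data.frame(id = seq_len(nrow(d)), frame = d$frame, t_s = d$t_s,
             x_um = d$x_um, y_um = d$y_um,
             quality = d$intensity, intensity = d$intensity)
}

#' Render a ground-truth simulation into a movie
#'
#' Each in-FOV particle is rendered as an integrated 2D Gaussian PSF
#' (exact pixel-area integral, so total rendered signal equals
#' `photonScale * intensity` up to mass outside the field of view), on a
#' constant background. With `noise = TRUE`, Poisson shot noise is applied
#' to the expected photon count, then Gaussian read noise is added, values
#' are clipped at zero and rounded to integers. With `noise = FALSE` the
#' noiseless expectation is returned (not rounded), which is convenient
#' for photometric tests.
#'
#' @param truth a [GroundTruth-class].
#' @param optics an [OpticsConfig-class]; defaults to the truth's optics.
#' @param seed integer seed for the noise draws.
#' @param noise apply shot and read noise.
#' @return a [TirfMovie-class].
#' @export
renderMovie <- function(truth, optics = truthOptics(truth), seed = 1L, noise = TRUE) {
  validObject(optics)
  px <- optics@pixelSizeUm
  if (optics@psfSigmaUm < px / 4)
    stop("PSF sigma below pixelSize/4: not renderable at this sampling")
  H <- optics@fovPx[1]; W <- optics@fovPx[2]; nfr <- optics@nFrames
  stack <- array(optics@backgroundLevel, dim = c(H, W, nfr))
  d <- truthTable(truth)
  d <- d[d$in_fov & d$frame <= nfr, , drop = FALSE]
  sig_px <- optics@psfSigmaUm / px
  win <- ceiling(5 * sig_px)

  for (i in seq_len(nrow(d))) {
    cx <- d$x_um[i] / px   # continuous pixel coordinate, pixel c spans [c-1, c]
    cy <- d$y_um[i] / px
    amp <- optics@photonScale * d$intensity[i]
    c0 <- max(1L, floor(cx) - win); c1 <- min(W, ceiling(cx) + win)
    r0 <- max(1L, floor(cy) - win); r1 <- min(H, ceiling(cy) + win)
    if (c0 > c1 || r0 > r1) next
    ex <- diff(stats::pnorm((c0 - 1):c1, mean = cx, sd = sig_px))
    ey <- diff(stats::pnorm((r0 - 1):r1, mean = cy, sd = sig_px))
    stack[r0:r1, c0:c1, d$frame[i]] <-
      stack[r0:r1, c0:c1, d$frame[i]] + amp * (ey %o% ex)
  }

  if (noise) {
    set.seed(as.integer(seed))
    n <- length(stack)
    stack[] <- stats::rpois(n, lambda = stack)
    if (optics@readNoiseSd > 0)
      stack[] <- stack + stats::rnorm(n, 0, optics@readNoiseSd)
    stack[] <- round(pmax(stack, 0))
  }
  tirfMovie(stack, pixelSizeUm = px, frameIntervalS = optics@frameIntervalS)
}

## ---------------------------------------------------------------------------
## Actin cortex simulation
## ---------------------------------------------------------------------------

#' Cortex-image simulation parameters
#'
#' @param imageSizePx integer (height, width) in pixels.
#' @param pixelSizeUm pixel size (um).
#' @param nClearances number of planted clearances.
#' @param clearanceAxesUm n x 2 matrix of ellipse semi-axes (um), or NULL to
#'   sample semi-axes uniformly from `axisRangeUm`.
#' @param axisRangeUm (lo, hi) range for sampled semi-axes (um).
#' @param orientations ellipse orientations (rad), or NULL to sample.
#' @param clearanceDepth fractional intensity drop inside a clearance
#'   (0 = invisible, 1 = fully dark).
#' @param filamentDensity filaments per um^2 of the meshwork texture.
#' @param filamentWidthUm Gaussian blur sigma applied to filaments (um).
#' @param rimWidthUm width of the bright compacted-actin rim around each
#'   clearance (um); 0 disables the rim.
#' @param noiseSd Gaussian noise sd as a fraction of the mean texture level.
#' @param edgeFalloffStart radius (as a fraction of the half image size) at
#'   which the peripheral signal falloff begins. The egg surface curves
#'   away from the evanescent field, so the cortex is bright only in a
#'   central patch; 0 disables the falloff.
#' @param edgeLevel residual intensity fraction far outside the bright patch.
#' @param rejectOverlap resample (and finally error) if planted clearances
#'   overlap.
#' @param seed integer seed.
#' @return a list of class `CortexSimSpec`.
#' @export
cortexSimSpec <- function(imageSizePx = c(256L, 256L), pixelSizeUm = 0.107,
                          nClearances = 5L, clearanceAxesUm = NULL,
                          axisRangeUm = c(0.8, 2.5), orientations = NULL,
                          clearanceDepth = 0.85, filamentDensity = 8,
                          filamentWidthUm = 0.08, rimWidthUm = 0.35,
                          noiseSd = 0.05, edgeFalloffStart = 0.70,
                          edgeLevel = 0.22, rejectOverlap = TRUE, seed = 1L) {
  spec <- list(imageSizePx = as.integer(imageSizePx), pixelSizeUm = pixelSizeUm,
               nClearances = as.integer(nClearances),
               clearanceAxesUm = clearanceAxesUm, axisRangeUm = axisRangeUm,
               orientations = orientations, clearanceDepth = clearanceDepth,
               filamentDensity = filamentDensity, filamentWidthUm = filamentWidthUm,
               rimWidthUm = rimWidthUm, noiseSd = noiseSd,
               edgeFalloffStart = edgeFalloffStart, edgeLevel = edgeLevel,
               rejectOverlap = rejectOverlap, seed = as.integer(seed))
  if (spec$pixelSizeUm <= 0 || any(spec$imageSizePx < 16L))
    stop("invalid image geometry")
  if (!is.null(spec$clearanceAxesUm)) {
    spec$clearanceAxesUm <- rbind(spec$clearanceAxesUm)
    if (any(spec$clearanceAxesUm <= 0)) stop("clearance axes must be > 0")
  }
  class(spec) <- "CortexSimSpec"
  spec
}

#' Simulate a cortical-actin image with planted clearances
#'
#' Builds a bright filamentous meshwork texture and stamps dark
#' quasi-elliptical clearances of known geometry into it, each surrounded
#' by a brighter rim of compacted actin. Returns the image together with
#' the analytic ground truth for every clearance: center, semi-axes,
#' orientation, true area pi*a*b and true circularity 4*pi*A/P^2 with the
#' ellipse perimeter from Ramanujan's approximation.
#'
#' @param spec a [cortexSimSpec()] list.
#' @return list with `image` (matrix, rows = y), `regions` (data.frame of
#'   true clearances) and `pixelSizeUm`.
#' @examples
#' sim <- simulateCortexImage(cortexSimSpec(nClearances = 2L, seed = 3))
#' sim$regions
#' @export
simulateCortexImage <- function(spec) {
  stopifnot(inherits(spec, "CortexSimSpec"))
  set.seed(spec$seed)
  H <- spec$imageSizePx[1]; W <- spec$imageSizePx[2]; px <- spec$pixelSizeUm
  h_um <- H * px; w_um <- W * px

  ## meshwork texture: a uniform membrane background plus sparse bright
  ## filaments (random blurred line segments). The background carries only
  ## pixel-scale noise (added last), so thresholding splits it into a
  ## percolating web and sub-resolution speckle rather than into coherent
  ## clearance-sized patches.
  fil <- matrix(0, H, W)
  nfil <- max(1L, round(spec$filamentDensity * h_um * w_um))
  for (i in seq_len(nfil)) {
    x0 <- stats::runif(1, 0, w_um); y0 <- stats::runif(1, 0, h_um)
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 0.5, 3)          # um
    s <- seq(0, len, by = px / 2)
    cc <- round((x0 + s * cos(ang)) / px + 0.5)
    rr <- round((y0 + s * sin(ang)) / px + 0.5)
    ok <- cc >= 1 & cc <= W & rr >= 1 & rr <= H
    idx <- cbind(rr[ok], cc[ok])
    fil[idx] <- fil[idx] + 1
  }
  sig_px <- max(0.5, spec$filamentWidthUm / px)
  fil <- EBImage::imageData(EBImage::gblur(fil, sigma = sig_px))
  img <- 0.55 + 0.45 * fil / max(mean(fil), 1e-12)

  ## plant clearances
  ax <- spec$clearanceAxesUm
  n <- spec$nClearances
  regions <- data.frame()
  if (n > 0L) {
    if (is.null(ax)) {
      ax <- cbind(stats::runif(n, spec$axisRangeUm[1], spec$axisRangeUm[2]),
                  stats::runif(n, spec$axisRangeUm[1], spec$axisRangeUm[2]))
    }
    if (nrow(ax) != n) stop("clearanceAxesUm must have one row per clearance")
    th <- spec$orientations
    if (is.null(th)) th <- stats::runif(n, 0, pi)

    ## place larger clearances first inside the bright central patch;
    ## restart the whole layout when sequential placement jams
    ord <- order(-pmax(ax[, 1], ax[, 2]))
    ax <- ax[ord, , drop = FALSE]; th <- th[ord]
    maxr <- pmax(ax[, 1], ax[, 2]) + spec$rimWidthUm
    half <- min(h_um, w_um) / 2
    rmax <- if (spec$edgeFalloffStart > 0)
      0.8 * spec$edgeFalloffStart * half else half - 2 * px
    centers <- matrix(NA_real_, n, 2)
    for (restart in 1:50) {
      centers[] <- NA_real_
      for (i in seq_len(n)) {
        for (try in 1:400) {
          cx <- stats::runif(1, w_um / 2 - rmax, w_um / 2 + rmax)
          cy <- stats::runif(1, h_um / 2 - rmax, h_um / 2 + rmax)
          ok <- sqrt((cx - w_um / 2)^2 + (cy - h_um / 2)^2) + maxr[i] <= rmax + 1e-9
          if (ok && spec$rejectOverlap && i > 1L) {
            prev <- seq_len(i - 1L)
            dd <- sqrt((centers[prev, 1] - cx)^2 + (centers[prev, 2] - cy)^2)
            ok <- all(dd > maxr[i] + maxr[prev] + 2 * px)
          }
          if (ok) { centers[i, ] <- c(cx, cy); break }
        }
        if (anyNA(centers[i, 1])) break
      }
      if (!anyNA(centers)) break
    }
    if (anyNA(centers))
      stop("could not place non-overlapping clearances; reduce n or axes")

    xs <- (col(img) - 0.5) * px
    ys <- (row(img) - 0.5) * px
    rim_gain <- 1.25 * max(img)
    for (i in seq_len(n)) {
      dx <- xs - centers[i, 1]; dy <- ys - centers[i, 2]
      u <- (dx * cos(th[i]) + dy * sin(th[i])) / ax[i, 1]
      v <- (-dx * sin(th[i]) + dy * cos(th[i])) / ax[i, 2]
      e2 <- u^2 + v^2
      inside <- e2 <= 1
      img[inside] <- img[inside] * (1 - spec$clearanceDepth)
      if (spec$rimWidthUm > 0) {
        rw <- spec$rimWidthUm / sqrt(ax[i, 1] * ax[i, 2])
        rim <- e2 > 1 & e2 <= (1 + rw)^2
        img[rim] <- pmax(img[rim], rim_gain)
      }
    }

    a <- ax[, 1]; b <- ax[, 2]
    per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))  # Ramanujan
    regions <- data.frame(
      id = seq_len(n), x_um = centers[, 1], y_um = centers[, 2],
      a_um = a, b_um = b, theta = th,
      area_um2 = pi * a * b,
      circularity = pmin(1, 4 * pi * (pi * a * b) / per^2))
  }

  ## peripheral falloff: the egg membrane curves away from the evanescent
  ## field, leaving a bright central cortex patch
  if (spec$edgeFalloffStart > 0) {
    half <- min(h_um, w_um) / 2
    r0 <- spec$edgeFalloffStart * half
    rr <- sqrt(((col(img) - 0.5) * px - w_um / 2)^2 +
               ((row(img) - 0.5) * px - h_um / 2)^2)
    fall <- ifelse(rr <= r0, 1,
                   spec$edgeLevel + (1 - spec$edgeLevel) *
                     exp(-((rr - r0) / (0.08 * half))^2))
    img <- img * fall
  }

  if (spec$noiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noiseSd * mean(img))

  list(image = img, regions = regions, pixelSizeUm = px)
}
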