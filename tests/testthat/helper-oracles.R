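## Independent oracles and fixture builders used across the suite.

## OLS oracle via lm(): slope, r2, two-sided p for the slope.
lmOracle <- function(times, y) {
  fit <- stats::lm(y ~ times)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       r2 = sm$r.squared,
       p = sm$coefficients[2, 4])
}

## Exhaustive minimum-cost matching oracle for the LAP objective:
## minimize sum of chosen d2 plus alt per unmatched source/target.
## dist2 is n x m with Inf marking inadmissible pairs.
## Returns the minimal total cost.
bruteForceMatchCost <- function(dist2, alt) {
  n <- nrow(dist2); m <- ncol(dist2)
  best <- Inf
  recurse <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) {
      total <- acc + alt * sum(!used)   # unmatched targets
      if (total < best) best <<- total
      return()
    }
    recurse(i + 1L, used, acc + alt)    # source i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(dist2[i, j]))
        recurse(i + 1L, `[<-`(used, j, TRUE), acc + dist2[i, j])
    }
  }
  recurse(1L, rep(FALSE, m), 0)
  best
}

## Total cost of a TrackSet's frame-pair links under the same objective,
## for one frame pair (fa -> fb).
linkCostOfResult <- function(spots, frags, fa, fb, alt) {
  ## frags: list of spot-id chains
  a_ids <- spots$id[spots$frame == fa]
  b_ids <- spots$id[spots$frame == fb]
  linked <- 0
  k <- 0L
  for (fr in frags) {
    pos <- match(c(fa, fb), spots$frame[match(fr, spots$id)])
    if (!anyNA(pos) && pos[2] == pos[1] + 1L) {
      ia <- match(fr[pos[1]], spots$id); ib <- match(fr[pos[2]], spots$id)
      linked <- linked + (spots$x_um[ia] - spots$x_um[ib])^2 +
        (spots$y_um[ia] - spots$y_um[ib])^2
      k <- k + 1L
    }
  }
  linked + alt * (length(a_ids) - k) + alt * (length(b_ids) - k)
}

## Simulated spot table for tracking-recovery tests: particles on a wide
## grid with bounded random steps and isolated interior missed frames.
gridParticleSpots <- function(nParticles = 20L, nFrames = 20L, spacingUm = 4,
                              stepSdUm = 0.08, missProb = 0, seed = 1) {
  set.seed(seed)
  ncol_grid <- ceiling(sqrt(nParticles))
  rows <- list()
  sid <- 0L
  for (p in seq_len(nParticles)) {
    gx <- ((p - 1L) %% ncol_grid) * spacingUm + 2
    gy <- ((p - 1L) %/% ncol_grid) * spacingUm + 2
    x <- gx + cumsum(c(0, pmin(pmax(rnorm(nFrames - 1, 0, stepSdUm), -0.3), 0.3)))
    y <- gy + cumsum(c(0, pmin(pmax(rnorm(nFrames - 1, 0, stepSdUm), -0.3), 0.3)))
    miss <- rep(FALSE, nFrames)
    if (missProb > 0) {
      u <- runif(nFrames)
      for (f in 2:(nFrames - 1L))
        if (u[f] < missProb && !miss[f - 1L]) miss[f] <- TRUE
    }
    for (f in which(!miss)) {
      sid <- sid + 1L
      rows[[sid]] <- data.frame(id = sid, particle = p, frame = f,
                                t_s = (f - 1) * 1, x_um = x[f], y_um = y[f],
                                quality = 100, intensity = 100)
    }
  }
  do.call(rbind, rows)
}

## Number of within-track identity switches against ground-truth particles.
identitySwitches <- function(trackset, spots_with_truth) {
  tt <- trackTable(trackset)
  truth <- spots_with_truth$particle[match(tt$id, spots_with_truth$id)]
  sum(vapply(split(truth, tt$track_id),
             function(v) length(unique(v)) - 1L, integer(1)))
}

## A movie with k well-separated rendered unit blobs on a fixed grid.
renderBlobGrid <- function(k = 25L, nFrames = 3L, pixelSizeUm = 0.107,
                           photonScale = 5000, noise = FALSE, seed = 1) {
  side <- ceiling(sqrt(k))
  spacing <- 2.4   # um, > 2x blob diameter
  fov_um <- side * spacing + 2
  fov_px <- as.integer(ceiling(fov_um / pixelSizeUm))
  opt <- opticsConfig(pixelSizeUm = pixelSizeUm, frameIntervalS = 1,
                      nFrames = nFrames, fovPx = c(fov_px, fov_px),
                      photonScale = photonScale, backgroundLevel = 100,
                      readNoiseSd = 3)
  pos <- data.frame(
    x = rep(seq_len(side), length.out = k) * spacing - spacing / 2 + 0.7,
    y = rep(seq_len(side), each = side)[1:k] * spacing - spacing / 2 + 0.7)
  d <- do.call(rbind, lapply(seq_len(k), function(i)
    data.frame(particle_id = i, label = "stationary", frame = seq_len(nFrames),
               t_s = seq_len(nFrames) - 1, x_um = pos$x[i], y_um = pos$y[i],
               z_um = 0, intensity = 1, in_fov = TRUE, visible = TRUE)))
  truth <- new("GroundTruth", data = d, optics = opt)
  list(truth = truth, movie = renderMovie(truth, opt, seed = seed, noise = noise),
       positions = pos, optics = opt)
}
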