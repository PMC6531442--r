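test_that("simulation is deterministic under a fixed seed", {
  opt <- opticsConfig(nFrames = 8L, fovPx = c(48L, 48L))
  beh <- list(behaviorSpec("diffusive", 5, diffusionCoeffUm2S = 0.01),
              behaviorSpec("appearing", 3, zStartUm = 0.3, zRateUmS = 0.01))
  g1 <- simulateTracks(beh, opt, seed = 42)
  g2 <- simulateTracks(beh, opt, seed = 42)
  expect_identical(truthTable(g1), truthTable(g2))

  m1 <- renderMovie(g1, opt, seed = 7)
  m2 <- renderMovie(g2, opt, seed = 7)
  expect_identical(frames(m1), frames(m2))

  s1 <- simulateCortexImage(cortexSimSpec(nClearances = 2L, seed = 5))
  s2 <- simulateCortexImage(cortexSimSpec(nClearances = 2L, seed = 5))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$regions, s2$regions)
})

test_that("stationary particles without jitter are frozen in place", {
  opt <- opticsConfig(nFrames = 6L, fovPx = c(32L, 32L))
  gt <- truthTable(simulateTracks(behaviorSpec("stationary", 2), opt, seed = 3))
  for (p in unique(gt$particle_id)) {
    d <- gt[gt$particle_id == p, ]
    expect_equal(length(unique(d$x_um)), 1L)
    expect_equal(length(unique(d$y_um)), 1L)
    expect_equal(length(unique(d$intensity)), 1L)
  }
})

test_that("evanescent intensity model follows the exponential closed form", {
  nfr <- 25L
  opt <- opticsConfig(nFrames = nfr, fovPx = c(48L, 48L), frameIntervalS = 1,
                      penetrationDepthUm = 0.12)
  zr <- 0.24 / ((nfr - 1) * 1)
  gt <- truthTable(simulateTracks(
    behaviorSpec("appearing", 1, zStartUm = 0.24, zRateUmS = zr), opt, seed = 2))
  ## z runs linearly 0.24 -> 0, so I(T)/I(0) = exp(0.24/0.12) = e^2
  expect_equal(gt$intensity[nfr] / gt$intensity[1], exp(2), tolerance = 1e-9)
  ## appearing: strictly increasing pre-noise intensity
  expect_true(all(diff(gt$intensity) > 0))

  gtv <- truthTable(simulateTracks(
    behaviorSpec("vanishing", 1, zStartUm = 0, zRateUmS = 0.01), opt, seed = 2))
  expect_true(all(diff(gtv$intensity) < 0))
})

test_that("diffusive mean squared step matches 2*D*dt per axis", {
  D <- 0.01; dt <- 1
  opt <- opticsConfig(nFrames = 2L, fovPx = c(512L, 512L), frameIntervalS = dt,
                      pixelSizeUm = 0.107)
  gt <- truthTable(simulateTracks(
    behaviorSpec("diffusive", 4000, diffusionCoeffUm2S = D), opt, seed = 11))
  gt <- gt[order(gt$particle_id, gt$frame), ]
  dx <- gt$x_um[gt$frame == 2] - gt$x_um[gt$frame == 1]
  dy <- gt$y_um[gt$frame == 2] - gt$y_um[gt$frame == 1]
  msd_axis <- mean(c(dx^2, dy^2))
  se <- 2 * D * dt * sqrt(2 / (2 * length(dx)))
  expect_lt(abs(msd_axis - 2 * D * dt), 3 * se)
})

test_that("renderer reproduces background and integrated blob photometry", {
  opt <- opticsConfig(nFrames = 2L, fovPx = c(48L, 48L), backgroundLevel = 100,
                      photonScale = 2000, pixelSizeUm = 0.107)
  empty <- new("GroundTruth",
               data = data.frame(particle_id = integer(), label = character(),
                                 frame = integer(), t_s = numeric(), x_um = numeric(),
                                 y_um = numeric(), z_um = numeric(), intensity = numeric(),
                                 in_fov = logical(), visible = logical()),
               optics = opt)
  mv0 <- renderMovie(empty, opt, noise = FALSE)
  expect_true(all(frames(mv0) == 100))

  one <- new("GroundTruth",
             data = data.frame(particle_id = 1L, label = "stationary", frame = 1:2,
                               t_s = c(0, 10), x_um = 2.5, y_um = 2.6, z_um = 0,
                               intensity = 1, in_fov = TRUE, visible = TRUE),
             optics = opt)
  mv1 <- renderMovie(one, opt, noise = FALSE)
  excess <- sum(frames(mv1)[, , 1]) - 100 * 48 * 48
  expect_equal(excess, 2000, tolerance = 1e-3)

  ## same seed -> bit-identical noisy movies
  expect_identical(frames(renderMovie(one, opt, seed = 9)),
                   frames(renderMovie(one, opt, seed = 9)))
})

test_that("cortex simulator reports analytic clearance geometry", {
  s0 <- simulateCortexImage(cortexSimSpec(nClearances = 0L, seed = 1))
  expect_equal(nrow(s0$regions), 0L)

  r <- 1.128
  s1 <- simulateCortexImage(cortexSimSpec(
    nClearances = 1L, clearanceAxesUm = cbind(r, r), seed = 2))
  expect_equal(s1$regions$area_um2, pi * r^2, tolerance = 1e-9)
  expect_equal(s1$regions$area_um2, 4.0, tolerance = 2e-3)
  expect_equal(s1$regions$circularity, 1.0, tolerance = 1e-9)
})

test_that("degenerate simulation inputs are rejected", {
  expect_error(simulateTracks(list(), opticsConfig()), "at least one")
  expect_error(opticsConfig(frameIntervalS = 0), "frameIntervalS")
  expect_error(opticsConfig(nFrames = 1L), "nFrames")
  expect_error(behaviorSpec("wandering", 1))
  opt <- opticsConfig(psfSigmaUm = 0.26 / 4, pixelSizeUm = 0.26, fovPx = c(32L, 32L))
  opt@psfSigmaUm <- 0.01  # force an unrenderable PSF past the constructor
  gt <- simulateTracks(behaviorSpec("stationary", 1), opticsConfig(), seed = 1)
  expect_error(renderMovie(gt, opt), "renderable")
})
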