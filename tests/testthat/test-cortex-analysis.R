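test_that("percentile threshold selects dark pixels and is inversion-symmetric", {
  img <- matrix(1, 20, 20); img[1:6, ] <- 0   # 30% dark
  m <- percentileThreshold(img)
  expect_equal(as.vector(m), as.vector(img == 0))

  ## inverted image with the dark-background flag toggled: identical mask
  m2 <- percentileThreshold(1 - img, darkBackground = TRUE)
  expect_identical(which(m2), which(m))

  expect_warning(mc <- percentileThreshold(matrix(3, 5, 5)), "constant")
  expect_false(any(mc))
})

test_that("clearance masks cover planted clearance pixels", {
  sim <- simulateCortexImage(cortexSimSpec(nClearances = 4L, axisRangeUm = c(0.8, 1.8), imageSizePx = c(320L, 320L), seed = 17))
  mask <- percentileThreshold(sim$image)
  px <- sim$pixelSizeUm
  xs <- (col(sim$image) - 0.5) * px
  ys <- (row(sim$image) - 0.5) * px
  for (i in seq_len(nrow(sim$regions))) {
    r <- sim$regions[i, ]
    u <- ((xs - r$x_um) * cos(r$theta) + (ys - r$y_um) * sin(r$theta)) / r$a_um
    v <- (-(xs - r$x_um) * sin(r$theta) + (ys - r$y_um) * cos(r$theta)) / r$b_um
    planted <- u^2 + v^2 <= 0.95^2   # interior, clear of the boundary band
    expect_gte(mean(mask[planted]), 0.95)
  }
})

test_that("region measurement recovers a planted disk and filters by area", {
  px <- 0.107
  H <- 220L
  mk_disk <- function(r_um) {
    m <- matrix(FALSE, H, H)
    d2 <- ((row(m) - H / 2)^2 + (col(m) - H / 2)^2) * px^2
    m[d2 <= r_um^2] <- TRUE
    m
  }
  ## true area 4 um^2 -> r = 1.128 um
  reg <- findClearances(mk_disk(sqrt(4 / pi)), px, clearanceConfig())
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$area_um2, 4.0, tolerance = 0.05 * 4)
  expect_gte(reg$circularity, 0.9)

  ## 0.5 um^2 and 50 um^2 fall outside the 1-40 um^2 filter
  expect_equal(nrow(findClearances(mk_disk(sqrt(0.5 / pi)), px, clearanceConfig())), 0L)
  expect_equal(nrow(findClearances(mk_disk(sqrt(50 / pi)), px, clearanceConfig())), 0L)
  ## ...but are measurable with wider bounds
  wide <- clearanceConfig(areaMinUm2 = 0.1, areaMaxUm2 = 100)
  expect_equal(findClearances(mk_disk(sqrt(50 / pi)), px, wide)$area_um2, 50,
               tolerance = 0.05 * 50)
})

test_that("digital disks and analytic squares have the expected circularity", {
  px <- 0.107
  for (r_px in c(10, 15, 25)) {
    H <- as.integer(4 * r_px + 8)
    m <- matrix(FALSE, H, H)
    m[(row(m) - H / 2)^2 + (col(m) - H / 2)^2 <= r_px^2] <- TRUE
    reg <- findClearances(m, px, clearanceConfig(areaMinUm2 = 0.01, areaMaxUm2 = 1e4,
                                                 circMin = 0, circMax = 1))
    expect_equal(nrow(reg), 1L)
    expect_gte(reg$circularity, 0.85)
    expect_lte(reg$circularity, 1.0)
  }
  ## continuous square: 4*pi*s^2 / (4s)^2 = pi/4
  expect_equal(circularity(1, 4), pi / 4, tolerance = 1e-12)
  expect_gte(circularity(1, 4), 0.2)  # passes the default filter
})

test_that("region filtering is monotone and conserves mask area", {
  sim <- simulateCortexImage(cortexSimSpec(nClearances = 5L, axisRangeUm = c(0.8, 1.6), imageSizePx = c(320L, 320L), seed = 23))
  mask <- percentileThreshold(sim$image)
  px <- sim$pixelSizeUm
  loose <- findClearances(mask, px, clearanceConfig(areaMinUm2 = 0.5, areaMaxUm2 = 60,
                                                    circMin = 0.1))
  tight <- findClearances(mask, px, clearanceConfig(areaMinUm2 = 2, areaMaxUm2 = 30,
                                                    circMin = 0.4))
  expect_gte(nrow(loose), nrow(tight))
  expect_lte(sum(loose$area_um2), sum(mask) * px^2)
})

test_that("8-connectivity merges diagonal components, 4 keeps them apart", {
  m <- matrix(FALSE, 30, 30)
  m[5:10, 5:10] <- TRUE
  m[11:16, 11:16] <- TRUE   # touches the first block only diagonally
  cfg8 <- clearanceConfig(areaMinUm2 = 0.01, areaMaxUm2 = 100, circMin = 0,
                          excludeBorder = FALSE)
  cfg4 <- clearanceConfig(areaMinUm2 = 0.01, areaMaxUm2 = 100, circMin = 0,
                          connectivity = 4L, excludeBorder = FALSE)
  expect_equal(nrow(findClearances(m, 0.2, cfg8)), 1L)
  expect_equal(nrow(findClearances(m, 0.2, cfg4)), 2L)
})

test_that("clearance frequency is count per analyzed area", {
  expect_equal(clearanceFrequency(data.frame(label = 1:5), 100), 0.05)
  expect_equal(clearanceFrequency(data.frame(label = integer()), 100), 0)
  expect_error(clearanceFrequency(data.frame(label = 1), 0), "> 0")
  sim <- simulateCortexImage(cortexSimSpec(nClearances = 6L, seed = 29,
                                           axisRangeUm = c(1.0, 2.0),
                                           imageSizePx = c(384L, 384L)))
  mask <- percentileThreshold(sim$image)
  reg <- findClearances(mask, sim$pixelSizeUm, clearanceConfig())
  roi <- prod(dim(sim$image)) * sim$pixelSizeUm^2
  expect_equal(clearanceFrequency(reg, roi), nrow(reg) / roi)
})

test_that("actin contact flags match an analytic distance oracle", {
  px <- 0.1
  img <- matrix(0, 60, 60)
  img[, 30] <- 10  # one vertical bright filament at x = 2.95 um
  xs <- seq(0.5, 5.5, by = 0.5)
  spots <- data.frame(x_um = xs, y_um = 3)
  flags <- actinContact(spots, img, px, radiusUm = 0.3, threshold = 5)
  ## pixel centers of the filament column are at x = 2.95
  oracle <- abs(xs - 2.95) <= 0.3
  expect_identical(flags, oracle)
  expect_error(actinContact(spots, img, px, radiusUm = 0.05), "radius")
})

test_that("cortex vs cytoplasm splits a phantom cell as constructed", {
  px <- 0.2
  H <- 80L
  d <- sqrt((row(matrix(0, H, H)) - 40)^2 + (col(matrix(0, H, H)) - 40)^2) * px
  cellMask <- d <= 6
  img <- matrix(1, H, H)
  rim <- cellMask & d > 5  # exactly the 1-um shell
  img[rim] <- 9

  r <- cortexVsCytoplasmIntensity(img, cellMask, px, shellWidthUm = 1)
  expect_gt(r$cortex_mean, r$cytoplasm_mean)
  ## digital erosion may misassign a thin band of pixels, so compare loosely
  expect_lt(r$cytoplasm_mean, 2)
  expect_gt(r$cortex_mean, 5)   # most shell pixels carry the bright rim

  u <- cortexVsCytoplasmIntensity(matrix(4, H, H), cellMask, px, 1)
  expect_equal(u$cortex_mean, u$cytoplasm_mean)

  expect_error(cortexVsCytoplasmIntensity(img, matrix(FALSE, H, H), px, 1), "empty")
  tiny <- d <= 0.9
  expect_error(cortexVsCytoplasmIntensity(img, tiny, px, 1), "consumes")
})

test_that("line profiles interpolate ramps and locate Gaussian peaks", {
  px <- 0.1
  ramp <- matrix(rep(1:50, each = 40), 40, 50)  # intensity = column index
  pr <- lineProfile(ramp, p0 = c(0.55, 2), p1 = c(4.55, 2), px)
  fit <- lm(pr$intensity ~ pr$distance_um)
  expect_equal(unname(coef(fit)[2]), 1 / px, tolerance = 1e-9)

  ## width-3 averaging equals width-1 on a uniform image
  uni <- matrix(5, 40, 40)
  p1 <- lineProfile(uni, c(1, 1), c(3, 3), px, widthPx = 1L)
  p3 <- lineProfile(uni, c(1, 1), c(3, 3), px, widthPx = 3L)
  expect_equal(p1$intensity, p3$intensity)

  ## peak of a rendered Gaussian lies at the crossing point
  opt <- opticsConfig(nFrames = 2L, fovPx = c(40L, 40L), pixelSizeUm = px,
                      backgroundLevel = 0, photonScale = 1000)
  gt <- new("GroundTruth",
            data = data.frame(particle_id = 1L, label = "stationary", frame = 1:2,
                              t_s = 0:1, x_um = 2, y_um = 2, z_um = 0,
                              intensity = 1, in_fov = TRUE, visible = TRUE),
            optics = opt)
  f1 <- frames(renderMovie(gt, opt, noise = FALSE))[, , 1]
  pr <- lineProfile(f1, c(0.5, 2), c(3.5, 2), px)
  expect_equal(pr$distance_um[which.max(pr$intensity)], 1.5, tolerance = px)

  expect_error(lineProfile(uni, c(1, 1), c(1, 1), px), "zero-length")
})
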