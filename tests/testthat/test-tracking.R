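test_that("frame-to-frame links respect the 1.0 um linking radius", {
  near <- data.frame(id = 1:2, frame = 1:2, x_um = c(0, 0.5), y_um = 0)
  frags <- linkFrames(near, linkingConfig())
  expect_length(frags, 1L)
  expect_equal(frags[[1]], 1:2)

  far <- data.frame(id = 1:2, frame = 1:2, x_um = c(0, 1.5), y_um = 0)
  frags <- linkFrames(far, linkingConfig())
  expect_length(frags, 2L)

  expect_error(linkFrames(data.frame(id = c(1, 1), frame = 1:2,
                                     x_um = 0, y_um = 0), linkingConfig()),
               "duplicate")
})

test_that("frame linking equals exhaustive minimum-cost matching", {
  cfg <- linkingConfig(maxLinkDistUm = 1.0)
  alt <- cfg@alternativeCostFactor * cfg@maxLinkDistUm^2
  set.seed(21)
  for (rep in 1:40) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    spots <- data.frame(
      id = seq_len(na + nb),
      frame = c(rep(1L, na), rep(2L, nb)),
      x_um = runif(na + nb, 0, 3), y_um = runif(na + nb, 0, 3))
    d2 <- outer(spots$x_um[1:na], spots$x_um[na + 1:nb], "-")^2 +
          outer(spots$y_um[1:na], spots$y_um[na + 1:nb], "-")^2
    d2[d2 > 1] <- Inf
    oracle <- bruteForceMatchCost(d2, alt)
    frags <- linkFrames(spots, cfg)
    got <- linkCostOfResult(spots, frags, 1L, 2L, alt)
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("gap closing obeys the distance cap and the maximum frame gap", {
  cfg <- linkingConfig(maxFrameGap = 2L)
  mk <- function(f2) data.frame(
    id = 1:4, frame = c(9L, 10L, f2, f2 + 1L),
    x_um = c(0, 0.05, 0.35, 0.4), y_um = 0)
  ## end frame 10, start frame 12, 0.3 um apart -> merged (frame gap 2)
  ts <- trackSpots(mk(12L), cfg)
  expect_equal(nTracks(ts), 1L)
  expect_equal(nrow(gapTable(ts)), 1L)
  expect_equal(gapTable(ts)$frame_before, 10L)
  expect_equal(gapTable(ts)$frame_after, 12L)
  ## start frame 13 -> frame gap 3 -> never merged
  ts3 <- trackSpots(mk(13L), cfg)
  expect_equal(nTracks(ts3), 2L)
  ## under the missing-frames convention a gap of two skipped frames closes
  tsm <- trackSpots(mk(13L), linkingConfig(maxFrameGap = 2L,
                                           gapConvention = "missing_frames"))
  expect_equal(nTracks(tsm), 1L)

  ## with maxFrameGap = 0 gap closing is the identity on fragments
  sp <- gridParticleSpots(nParticles = 4L, nFrames = 6L, missProb = 0.3, seed = 5)
  cfg0 <- linkingConfig(maxFrameGap = 0L)
  frags <- linkFrames(sp, cfg0)
  ts0 <- closeGaps(frags, sp, cfg0)
  expect_equal(nTracks(ts0), length(frags))
  expect_equal(nrow(gapTable(ts0)), 0L)
})

test_that("gap-closing assignment equals exhaustive minimum-cost matching", {
  cfg <- linkingConfig(maxGapDistUm = 1.0, maxFrameGap = 2L)
  alt <- cfg@alternativeCostFactor * cfg@maxGapDistUm^2
  set.seed(8)
  for (rep in 1:20) {
    ## three 2-spot fragments ending at frame 5, three starting at frame 7
    ends <- data.frame(x = runif(3, 0, 2.5), y = runif(3, 0, 2.5))
    starts <- data.frame(x = runif(3, 0, 2.5), y = runif(3, 0, 2.5))
    spots <- data.frame(
      id = 1:12,
      frame = c(rep(c(4L, 5L), 3), rep(c(7L, 8L), 3)),
      x_um = c(rbind(ends$x, ends$x), rbind(starts$x, starts$x)),
      y_um = c(rbind(ends$y, ends$y), rbind(starts$y, starts$y)))
    frags <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L), c(9L, 10L), c(11L, 12L))
    ts <- closeGaps(frags, spots, cfg)
    d2 <- outer(ends$x, starts$x, "-")^2 + outer(ends$y, starts$y, "-")^2
    d2[d2 > 1] <- Inf
    oracle <- bruteForceMatchCost(d2, alt)
    ## cost attained by the returned bridges
    gp <- gapTable(ts)
    got <- 0; k <- 0L
    tt <- trackTable(ts)
    for (tid in unique(tt$track_id)) {
      d <- tt[tt$track_id == tid, ]
      j <- which(diff(d$frame) == 2L)
      for (jj in j) {
        got <- got + (d$x_um[jj] - d$x_um[jj + 1])^2 + (d$y_um[jj] - d$y_um[jj + 1])^2
        k <- k + 1L
      }
    }
    got <- got + alt * (3 - k) * 2
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_equal(nrow(gp), k)
  }
})

test_that("tracking conserves spots and never doubles frames in a track", {
  sp <- gridParticleSpots(nParticles = 12L, nFrames = 10L, missProb = 0.1, seed = 9)
  ts <- trackSpots(sp, linkingConfig())
  tt <- trackTable(ts)
  expect_setequal(tt$id, sp$id)          # every spot in exactly one track
  expect_equal(anyDuplicated(tt$id), 0L)
  for (tid in unique(tt$track_id)) {
    d <- tt[tt$track_id == tid, ]
    expect_equal(anyDuplicated(d$frame), 0L)
    expect_true(all(diff(d$frame) > 0))
  }
})

test_that("well-separated particles are recovered without identity switches", {
  sp <- gridParticleSpots(nParticles = 20L, nFrames = 15L, spacingUm = 4,
                          missProb = 0, seed = 13)
  ts <- trackSpots(sp, linkingConfig())
  expect_equal(nTracks(ts), 20L)
  expect_equal(identitySwitches(ts, sp), 0L)

  ## single-frame dropouts are bridged back into the same 20 tracks
  spm <- gridParticleSpots(nParticles = 20L, nFrames = 15L, spacingUm = 4,
                           missProb = 0.12, seed = 14)
  tsm <- trackSpots(spm, linkingConfig())
  expect_equal(nTracks(tsm), 20L)
  expect_equal(identitySwitches(tsm, spm), 0L)
})

test_that("empty input produces an empty track set", {
  ts <- trackSpots(data.frame(id = integer(), frame = integer(),
                              x_um = numeric(), y_um = numeric()))
  expect_equal(nTracks(ts), 0L)
  expect_equal(nrow(trackTable(ts)), 0L)
})
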