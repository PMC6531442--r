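test_that("pointwise features compute displacement and percent-of-max", {
  tr <- data.frame(frame = 1:3, t_s = 0:2, x_um = c(0, 0.3, 0.3),
                   y_um = c(0, 0.4, 0.4), intensity = c(100, 250, 500))
  pf <- pointwiseFeatures(tr)
  expect_equal(pf$pct_max, c(20, 50, 100))
  expect_equal(pf$step_um, c(NA, 0.5, 0))
  expect_equal(pf$cum_um, c(0, 0.5, 0.5))
  expect_equal(max(pf$pct_max), 100)

  flat <- data.frame(frame = 1:3, t_s = 0:2, x_um = 0, y_um = 0, intensity = 500)
  expect_true(all(pointwiseFeatures(flat)$pct_max == 100))

  dark <- data.frame(frame = 1:3, t_s = 0:2, x_um = 0, y_um = 0, intensity = 0)
  pfd <- pointwiseFeatures(dark)
  expect_true(all(is.na(pfd$pct_max)))
  expect_false(attr(pfd, "pct_max_defined"))
})

test_that("regression statistics agree with the lm oracle to 1e-9", {
  ## exact line
  st <- regressionStats(0:4, c(20, 40, 60, 80, 100))
  expect_equal(st$slope, 20); expect_equal(st$r2, 1)
  ## constant series: slope 0, r2 defined as 0
  stc <- regressionStats(0:4, rep(50, 5))
  expect_equal(stc$slope, 0); expect_equal(stc$r2, 0); expect_equal(stc$p, 1)
  ## short series undefined
  expect_true(is.na(regressionStats(0:1, c(1, 2))$slope))
  expect_error(regressionStats(c(0, 0, 1), c(1, 2, 3)), "strictly increasing")

  set.seed(31)
  for (rep in 1:15) {
    t <- sort(runif(30, 0, 50))
    y <- 100 - 1.3 * t + rnorm(30, 0, 8)
    got <- regressionStats(t, y)
    want <- lmOracle(t, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-9)
    expect_equal(got$r2, want$r2, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})

test_that("profile classification follows the R2/p/slope criteria", {
  cr <- profileCriteria()  # R2 > 0.6, p < 0.05
  expect_equal(classifyProfile(list(slope = 2, r2 = 0.9, p = 0.001), cr), "appearing")
  expect_equal(classifyProfile(list(slope = -2, r2 = 0.9, p = 0.001), cr), "vanishing")
  expect_equal(classifyProfile(list(slope = 2, r2 = 0.5, p = 0.001), cr), "neither")
  expect_equal(classifyProfile(list(slope = 2, r2 = 0.9, p = 0.2), cr), "neither")
  expect_equal(classifyProfile(list(slope = 0, r2 = 0.9, p = 0.001), cr), "neither")
  expect_equal(classifyProfile(list(slope = NA, r2 = NA, p = NA), cr), "neither")
})

test_that("duration classes partition tracks by the 8 s / full-span rule", {
  th <- durationThresholds()  # short < 8 s, long = full span
  span <- c(1L, 50L); dt <- 1
  expect_equal(classifyDuration(1L, 50L, span, dt, th), "long")
  expect_equal(classifyDuration(10L, 15L, span, dt, th), "short")   # 5 s
  expect_equal(classifyDuration(11L, 31L, span, dt, th), "medium")  # 20 s
  expect_equal(classifyDuration(2L, 9L, span, dt, th), "short")     # 7 s
  expect_equal(classifyDuration(2L, 10L, span, dt, th), "medium")   # 8 s boundary
  ## every track gets exactly one class
  set.seed(2)
  for (i in 1:50) {
    f0 <- sample(1:50, 1); f1 <- sample(f0:50, 1)
    cls <- classifyDuration(f0, f1, span, dt, th)
    expect_true(cls %in% c("short", "medium", "long"))
    expect_length(cls, 1L)
  }
})

test_that("stationary flag needs full span, flat profile and small displacement", {
  span <- c(1L, 50L)
  expect_true(isStationary(1L, 50L, 0.1, "neither", span, 0.5))
  expect_false(isStationary(1L, 50L, 0.1, "appearing", span, 0.5))
  expect_false(isStationary(3L, 50L, 0.1, "neither", span, 0.5))
  expect_false(isStationary(1L, 50L, 0.8, "neither", span, 0.5))
})

test_that("group comparisons match closed-form oracles", {
  ## identical samples: t statistic exactly 0, p = 1
  r <- compareGroups(c(1, 2, 3, 4), c(1, 2, 3, 4), mode = "t_test")
  expect_equal(r$statistic, 0); expect_equal(r$p, 1)
  expect_error(compareGroups(c(1, 1), c(1, 1), mode = "t_test"), "variance")

  ## N-1 chi-squared vs Pearson oracle
  a <- c(30, 70); b <- c(50, 50)
  got <- compareGroups(a, b, mode = "n_minus_1_chi2")
  pearson <- unname(suppressWarnings(
    stats::chisq.test(rbind(a, b), correct = FALSE)$statistic))
  N <- sum(a) + sum(b)
  expect_equal(got$statistic, pearson * (N - 1) / N, tolerance = 1e-9)
  expect_equal(got$p, stats::pchisq(pearson * (N - 1) / N, 1, lower.tail = FALSE))

  set.seed(12)
  for (i in 1:10) {
    tab <- matrix(sample(5:80, 4), 2)
    got <- compareGroups(tab[1, ], tab[2, ], mode = "n_minus_1_chi2")
    pearson <- unname(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic))
    expect_equal(got$statistic, pearson * (sum(tab) - 1) / sum(tab),
                 tolerance = 1e-9)
  }
  expect_error(compareGroups(c(0, 0), c(1, 2), mode = "n_minus_1_chi2"), "marginal")
})

test_that("minimum enclosing ellipse contains its points", {
  ## two points degenerate to the segment
  e2 <- boundingEllipse(c(0, 2), c(0, 0))
  expect_equal(e2$a, 1); expect_equal(e2$b, 0)
  expect_equal(e2$cx, 1); expect_equal(e2$cy, 0)
  ## identical points give a zero ellipse
  e0 <- boundingEllipse(c(1, 1), c(2, 2))
  expect_equal(e0$a, 0); expect_equal(e0$b, 0)

  ## unit square: within 0.1% of the circumscribed circle
  es <- boundingEllipse(c(0, 1, 1, 0), c(0, 0, 1, 1))
  circ_area <- pi * 0.5
  expect_lte(pi * es$a * es$b, circ_area * 1.001)
  inEllipse <- function(e, x, y, slack = 1e-4) {
    dx <- x - e$cx; dy <- y - e$cy
    u <- (dx * cos(e$theta) + dy * sin(e$theta)) / e$a
    v <- (-dx * sin(e$theta) + dy * cos(e$theta)) / max(e$b, 1e-12)
    all(u^2 + v^2 <= 1 + slack)
  }
  expect_true(inEllipse(es, c(0, 1, 1, 0), c(0, 0, 1, 1)))

  set.seed(6)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    e <- boundingEllipse(x, y)
    expect_true(inEllipse(e, x, y))
  }
})

test_that("classification is invariant to intensity rescaling", {
  set.seed(44)
  cr <- profileCriteria()
  for (i in 1:30) {
    n <- 30
    trend <- sample(c(-1.5, 0, 1.5), 1)
    base <- 50 + trend * (1:n) + rnorm(n, 0, 5)
    base <- pmax(base, 1)
    for (s in c(0.01, 1, 1000)) {
      tr <- data.frame(frame = 1:n, t_s = 0:(n - 1), x_um = 0, y_um = 0,
                       intensity = base * s)
      pf <- pointwiseFeatures(tr)
      st <- regressionStats(pf$t_s, pf$pct_max)
      if (s == 0.01) ref <- classifyProfile(st, cr)
      expect_equal(classifyProfile(st, cr), ref)
    }
  }
})

test_that("trackFeatures aggregates one classified row per track", {
  sp <- gridParticleSpots(nParticles = 6L, nFrames = 12L, seed = 3)
  sp$intensity <- 100 + 10 * sp$frame * (sp$particle %% 2)  # half rising
  ts <- trackSpots(sp, linkingConfig())
  ft <- trackFeatures(ts, movieSpan = c(1L, 12L), intervalS = 1)
  expect_equal(nrow(ft), 6L)
  expect_true(all(ft$duration_class %in% c("short", "medium", "long")))
  expect_true(all(ft$profile_class %in% c("appearing", "vanishing", "neither")))
  expect_true(all(ft$r2 >= 0 & ft$r2 <= 1, na.rm = TRUE))
  expect_true(all(ft$duration_s == (12 - 1) * 1))
  ## rising-intensity tracks are classified appearing
  rising <- ft$track_id[ft$slope_pct_per_s > 1]
  expect_true(all(ft$profile_class[ft$track_id %in% rising] == "appearing"))
})
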