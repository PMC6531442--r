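## Track library: per-timepoint derived values, per-track aggregates,
## duration classes, appearing/vanishing classification, group comparisons.

#' Per-timepoint derived values for one track
#'
#' Computes, for each detection of a track: the step displacement from the
#' previous detection, the cumulative displacement from the track origin,
#' and the intensity as a percentage of the track's maximum intensity.
#'
#' @param track data.frame with `frame`, `t_s`, `x_um`, `y_um`, `intensity`
#'   (one track, any row order).
#' @return the track in frame order with added columns `step_um`
#'   (NA for the first detection), `cum_um` and `pct_max`. When the track
#'   maximum intensity is not positive, `pct_max` is NA and the result
#'   carries attribute `pct_max_defined = FALSE`.
#' @examples
#' tr <- data.frame(frame = 1:3, t_s = 0:2, x_um = c(0, 0.3, 0.3),
#'                  y_um = c(0, 0.4, 0.4), intensity = c(100, 250, 500))
#' pointwiseFeatures(tr)
#' @export
pointwiseFeatures <- function(track) {
  if (!nrow(track)) stop("track is empty")
  track <- track[order(track$frame), , drop = FALSE]
  dx <- diff(track$x_um); dy <- diff(track$y_um)
  track$step_um <- c(NA, sqrt(dx^2 + dy^2))
  track$cum_um <- sqrt((track$x_um - track$x_um[1])^2 +
                       (track$y_um - track$y_um[1])^2)
  mx <- max(track$intensity)
  if (is.na(mx) || mx <= 0) {
    track$pct_max <- NA_real_
    attr(track, "pct_max_defined") <- FALSE
  } else {
    track$pct_max <- 100 * track$intensity / mx
    attr(track, "pct_max_defined") <- TRUE
  }
  track
}

#' Closed-form simple linear regression statistics
#'
#' Ordinary least squares of `y` on `t` by the normal equations, returning
#' the slope, the coefficient of determination and the two-sided p-value
#' of the t-test on the slope with n - 2 degrees of freedom. R^2 is
#' defined as 0 when the response has zero variance (so a flat intensity
#' profile is classifiable as "neither" rather than undefined).
#'
#' @param times strictly increasing numeric vector.
#' @param y response values (percent-of-max intensity).
#' @param minPoints minimum number of points; fewer returns NA statistics.
#' @return list with `slope`, `r2`, `p`, `n`.
#' @examples
#' regressionStats(0:4, c(20, 40, 60, 80, 100))
#' @export
regressionStats <- function(times, y, minPoints = 3L) {
  n <- length(times)
  if (n != length(y)) stop("times and y must have equal length")
  if (n < minPoints || anyNA(times) || anyNA(y))
    return(list(slope = NA_real_, r2 = NA_real_, p = NA_real_, n = n))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  tb <- mean(times); yb <- mean(y)
  sxx <- sum((times - tb)^2)
  sxy <- sum((times - tb) * (y - yb))
  syy <- sum((y - yb)^2)
  slope <- sxy / sxx
  ssr <- syy - slope * sxy          # residual sum of squares
  r2 <- if (syy > 0) 1 - ssr / syy else 0
  se2 <- ssr / (n - 2) / sxx
  p <- if (se2 > 0) {
    tval <- slope / sqrt(se2)
    2 * stats::pt(-abs(tval), df = n - 2)
  } else if (slope != 0) 0 else 1   # exact fit: p -> 0 unless flat
  list(slope = slope, r2 = max(0, min(1, r2)), p = p, n = n)
}

#' Classify a track's intensity profile
#'
#' Applies the appearing/vanishing criteria to the percent-of-max
#' regression statistics: `appearing` when R^2 > r2Min, p < pMax and the
#' slope is positive; `vanishing` with a negative slope; `neither`
#' otherwise (including undefined statistics and zero slope).
#'
#' @param stats list with `slope`, `r2`, `p` (from [regressionStats()]).
#' @param criteria a [ProfileCriteria-class].
#' @return `"appearing"`, `"vanishing"` or `"neither"`.
#' @examples
#' classifyProfile(list(slope = 2, r2 = 0.9, p = 0.001), profileCriteria())
#' @export
classifyProfile <- function(stats, criteria = profileCriteria()) {
  if (is.na(stats$slope) || is.na(stats$r2) || is.na(stats$p)) return("neither")
  if (stats$r2 > criteria@r2Min && stats$p < criteria@pMax) {
    if (stats$slope > 0) return("appearing")
    if (stats$slope < 0) return("vanishing")
  }
  "neither"
}

#' Classify a track's duration
#'
#' `long` when the track is present at both the movie's first and last
#' frame (with `longRule` on) or when its duration equals the full span;
#' otherwise `short` when shorter than `shortMaxS`; otherwise `medium`.
#'
#' @param firstFrame,lastFrame first and last frame of the track.
#' @param movieSpan integer (first frame, last frame) of the movie.
#' @param intervalS frame interval (s).
#' @param thresholds a [DurationThresholds-class].
#' @return `"short"`, `"medium"` or `"long"`.
#' @export
classifyDuration <- function(firstFrame, lastFrame, movieSpan, intervalS,
                             thresholds = durationThresholds()) {
  full <- if (thresholds@longRule)
    firstFrame <= movieSpan[1] && lastFrame >= movieSpan[2]
  else
    (lastFrame - firstFrame) >= (movieSpan[2] - movieSpan[1])
  if (full) return("long")
  dur <- (lastFrame - firstFrame) * intervalS
  if (dur < thresholds@shortMaxS) "short" else "medium"
}

#' Is a track stationary?
#'
#' A track is stationary when it spans the whole movie (present at the
#' first and last frame), its intensity profile is classified `neither`
#' (brightness does not change systematically), and its net displacement
#' does not exceed `maxNetDisplacementUm`.
#'
#' @param firstFrame,lastFrame track extent in frames.
#' @param netDisplacementUm net first-to-last displacement (um).
#' @param profileClass output of [classifyProfile()].
#' @param movieSpan integer (first frame, last frame) of the movie.
#' @param maxNetDisplacementUm displacement cap (um), default 0.5
#'   (sub-blob-diameter).
#' @return logical flag.
#' @export
isStationary <- function(firstFrame, lastFrame, netDisplacementUm, profileClass,
                         movieSpan, maxNetDisplacementUm = 0.5) {
  firstFrame <= movieSpan[1] && lastFrame >= movieSpan[2] &&
    profileClass == "neither" && netDisplacementUm <= maxNetDisplacementUm
}

#' Minimum-area enclosing ellipse of a point set
#'
#' Khachiyan's algorithm for the minimum-volume enclosing ellipsoid in 2D
#' at tolerance 1e-7. Degenerate inputs are handled explicitly: identical
#' points give a zero-axis ellipse and collinear points a segment
#' (minor axis 0). With `method = "covariance"` a 2-sigma covariance
#' ellipse is returned instead.
#'
#' @param x,y point coordinates (um).
#' @param tol Khachiyan convergence tolerance.
#' @param method `"mve"` (minimum enclosing) or `"covariance"`.
#' @return list with `cx`, `cy`, `a` (semi-major), `b` (semi-minor),
#'   `theta` (radians).
#' @examples
#' boundingEllipse(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' @export
boundingEllipse <- function(x, y, tol = 1e-7, method = c("mve", "covariance")) {
  method <- match.arg(method)
  P <- unique(cbind(x, y))
  n <- nrow(P)
  cx <- mean(P[, 1]); cy <- mean(P[, 2])
  if (n == 1L) return(list(cx = P[1, 1], cy = P[1, 2], a = 0, b = 0, theta = 0))

  C <- stats::cov(P)
  ev <- eigen(C, symmetric = TRUE)
  if (method == "covariance") {
    a <- 2 * sqrt(max(ev$values[1], 0)); b <- 2 * sqrt(max(ev$values[2], 0))
    th <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
    return(list(cx = cx, cy = cy, a = a, b = b, theta = th %% pi))
  }

  ## rank-deficient (collinear): degenerate segment along the major axis
  if (ev$values[2] <= 1e-12 * max(ev$values[1], 1e-300)) {
    u <- ev$vectors[, 1]
    s <- P %*% u
    ctr <- (max(s) + min(s)) / 2
    cc <- c(cx, cy) + as.numeric(ctr - mean(s)) * u
    return(list(cx = cc[1], cy = cc[2], a = (max(s) - min(s)) / 2, b = 0,
                theta = atan2(u[2], u[1]) %% pi))
  }

  ## Khachiyan iteration
  d <- 2
  Q <- rbind(t(P), 1)
  u <- rep(1 / n, n)
  for (it in 1:5000) {
    X <- Q %*% (u * t(Q))
    M <- colSums(Q * solve(X, Q))
    j <- which.max(M)
    mx <- M[j]
    if (mx <= (d + 1) * (1 + tol)) break
    step <- (mx - d - 1) / ((d + 1) * (mx - 1))
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  c0 <- as.numeric(t(P) %*% u)
  A <- solve(t(P) %*% (u * P) - c0 %*% t(c0)) / d
  ## inflate minimally so every input point is contained exactly
  dxy <- sweep(P, 2, c0)
  e2max <- max(rowSums((dxy %*% A) * dxy))
  if (e2max > 1) A <- A / e2max
  ea <- eigen(A, symmetric = TRUE)
  ax <- 1 / sqrt(pmax(ea$values, 1e-300))
  th <- atan2(ea$vectors[2, 2], ea$vectors[1, 2])   # eigenvector of smaller eigenvalue = major axis
  list(cx = c0[1], cy = c0[2], a = ax[2], b = ax[1], theta = th %% pi)
}

#' Per-track aggregate features and classes
#'
#' Computes the per-track feature table: duration, start and end times,
#' net (total) displacement, path length, mean step speed, mean intensity,
#' the percent-of-max regression aggregates (slope in percent per second,
#' R^2, p-value), the bounding ellipse, the duration class, the intensity
#' profile class and the stationary flag.
#'
#' @param trackset a [TrackSet-class] whose spots carry `t_s` and `intensity`.
#' @param movieSpan integer (first frame, last frame) of the movie;
#'   defaults to the observed spot range.
#' @param intervalS frame interval (s); inferred from `t_s` when NULL.
#' @param criteria a [ProfileCriteria-class].
#' @param thresholds a [DurationThresholds-class].
#' @param maxNetDisplacementUm stationary displacement cap (um).
#' @param ellipseMethod `"mve"` or `"covariance"`.
#' @return data.frame, one row per track.
#' @export
trackFeatures <- function(trackset, movieSpan = NULL, intervalS = NULL,
                          criteria = profileCriteria(),
                          thresholds = durationThresholds(),
                          maxNetDisplacementUm = 0.5,
                          ellipseMethod = "mve") {
  sp <- trackTable(trackset)
  if (!nrow(sp)) return(data.frame())
  if (is.null(movieSpan)) movieSpan <- range(sp$frame)
  if (is.null(intervalS)) {
    dts <- diff(sort(unique(sp$t_s)))
    intervalS <- if (length(dts)) min(dts) else 1
  }
  rows <- lapply(split(sp, sp$track_id), function(tr) {
    tr <- pointwiseFeatures(tr)
    n <- nrow(tr)
    f0 <- tr$frame[1]; f1 <- tr$frame[n]
    dur <- (f1 - f0) * intervalS
    net <- tr$cum_um[n]
    path <- sum(tr$step_um[-1])
    st <- if (isTRUE(attr(tr, "pct_max_defined")))
      regressionStats(tr$t_s, tr$pct_max, minPoints = criteria@minPoints)
    else list(slope = NA_real_, r2 = NA_real_, p = NA_real_, n = n)
    pclass <- classifyProfile(st, criteria)
    dclass <- classifyDuration(f0, f1, movieSpan, intervalS, thresholds)
    ell <- boundingEllipse(tr$x_um, tr$y_um, method = ellipseMethod)
    data.frame(
      track_id = tr$track_id[1], n_spots = n,
      start_t_s = tr$t_s[1], end_t_s = tr$t_s[n], duration_s = dur,
      total_displacement_um = net, path_length_um = if (n > 1) path else 0,
      mean_speed_um_s = if (dur > 0) path / dur else 0,
      mean_intensity = mean(tr$intensity), max_intensity = max(tr$intensity),
      slope_pct_per_s = st$slope, r2 = st$r2, p_value = st$p,
      ellipse_cx = ell$cx, ellipse_cy = ell$cy,
      ellipse_a = ell$a, ellipse_b = ell$b, ellipse_theta = ell$theta,
      duration_class = dclass, profile_class = pclass,
      stationary = isStationary(f0, f1, net, pclass, movieSpan,
                                maxNetDisplacementUm))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two groups of measurements or class counts
#'
#' `mode = "t_test"`: unpaired two-tailed Student's t-test (equal
#' variances) between two numeric samples. `mode = "n_minus_1_chi2"`: the
#' N-1 chi-squared test for comparing percentages, i.e. the Pearson
#' chi-squared statistic scaled by (N-1)/N, referred to a chi-squared
#' distribution with (k-1) degrees of freedom for a 2 x k table.
#'
#' @param a,b for `t_test`: numeric vectors; for `n_minus_1_chi2`: count
#'   vectors of equal length k (the two rows of the 2 x k table).
#' @param mode `"t_test"` or `"n_minus_1_chi2"`.
#' @return list with `statistic` and `p`.
#' @examples
#' compareGroups(c(30, 70), c(50, 50), mode = "n_minus_1_chi2")
#' @export
compareGroups <- function(a, b, mode = c("t_test", "n_minus_1_chi2")) {
  mode <- match.arg(mode)
  if (mode == "t_test") {
    if (length(a) < 2L || length(b) < 2L) stop("t-test needs >= 2 values per group")
    if (stats::var(a) == 0 && stats::var(b) == 0)
      stop("zero variance in both samples: t statistic undefined")
    ht <- stats::t.test(a, b, var.equal = TRUE)
    return(list(statistic = unname(ht$statistic), p = ht$p.value))
  }
  tab <- rbind(a, b)
  if (ncol(tab) < 2L) stop("chi-squared needs a 2 x k table with k >= 2")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the contingency table")
  N <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / N
  chi2 <- sum((tab - expd)^2 / expd)
  stat <- chi2 * (N - 1) / N
  df <- ncol(tab) - 1L
  list(statistic = stat, p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
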