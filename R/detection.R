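## Difference-of-Gaussians spot detection with sub-pixel localization.

#' Difference-of-Gaussians detector response
#'
#' Computes G(sigma1) * I - G(sigma2) * I where sigma1 is matched to the
#' expected blob scale, sigma1 = (blobDiameter/2) / sqrt(2) (the classic
#' scale-space relation for a Gaussian blob), and sigma2 = ratio * sigma1.
#' The response is rescaled so that a unit-amplitude Gaussian blob of the
#' nominal diameter produces a peak response of 1: for Gaussian-Gaussian
#' convolution the raw peak is 1/2 - 1/(1 + ratio^2), and the response is
#' divided by that factor. The operator is linear in image intensity, so
#' quality values are in (blob-amplitude) image-intensity units.
#'
#' @param image numeric matrix (rows = y).
#' @param blobDiameterUm expected blob diameter (um).
#' @param pixelSizeUm pixel size (um).
#' @param dogSigmaRatio sigma2/sigma1, default 1.6.
#' @return response matrix of the same size.
#' @examples
#' img <- matrix(5, 32, 32)
#' range(dogResponse(img, 0.6, 0.107))  # constant image -> 0
#' @export
dogResponse <- function(image, blobDiameterUm, pixelSizeUm, dogSigmaRatio = 1.6) {
  if (blobDiameterUm <= 0 || pixelSizeUm <= 0) stop("diameter and pixel size must be > 0")
  if (anyNA(image)) stop("image contains NaN/NA values")
  s1 <- (blobDiameterUm / 2) / sqrt(2) / pixelSizeUm
  if (s1 < 0.25) stop("DoG scale below 0.25 px: image is undersampled for this blob size")
  s2 <- dogSigmaRatio * s1
  g1 <- EBImage::imageData(EBImage::gblur(image, sigma = s1))
  g2 <- EBImage::imageData(EBImage::gblur(image, sigma = s2))
  peak <- 0.5 - 1 / (1 + dogSigmaRatio^2)
  (g1 - g2) / peak
}

#' Otsu auto-threshold on spot qualities
#'
#' Computes Otsu's threshold on a 256-bin histogram of the observed
#' quality range, used to auto-filter detections after the initial
#' quality cut.
#'
#' @param qualities numeric vector (>= 2 values).
#' @return the threshold value.
#' @examples
#' autoQualityThreshold(c(rep(100, 10), rep(1000, 10)))
#' @export
autoQualityThreshold <- function(qualities) {
  if (length(qualities) < 2L) stop("need at least 2 quality values")
  rng <- range(qualities)
  if (diff(rng) == 0) {
    warning("all quality values identical; returning that value")
    return(rng[1])
  }
  nb <- 256L
  breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(pmin(nb, findInterval(qualities, breaks, rightmost.closed = TRUE)), nb)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nb + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nb]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  sigma_b <- sigma_b[-nb]
  ## the criterion is flat between separated modes: take the plateau midpoint
  best <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  k <- as.integer(round(mean(best)))
  breaks[k + 1L]
}

#' Detect spots in a calibrated movie
#'
#' Per frame: compute the DoG response, find local maxima with minimum
#' separation equal to the blob radius (greedy non-maximum suppression in
#' decreasing response order; ties broken by higher raw intensity, then
#' lower (y, x)), discard maxima with quality below `qualityMin` (and
#' below the Otsu auto-threshold when `useAutoThreshold` is on), refine
#' positions by a quadratic fit of the 3x3 response neighborhood (offsets
#' clamped to half a pixel), and measure intensity as the summed signal
#' within the blob radius minus the local median background estimated in
#' a 1.5-2.5 radius annulus.
#'
#' @param movie a [TirfMovie-class].
#' @param cfg a [DetectionConfig-class].
#' @return data.frame of spots sorted by (frame, quality descending) with
#'   columns `id`, `frame`, `t_s`, `x_um`, `y_um`, `quality`, `intensity`.
#' @export
detectSpots <- function(movie, cfg = detectionConfig()) {
  stopifnot(is(movie, "TirfMovie"), is(cfg, "DetectionConfig"))
  stack <- frames(movie)
  px <- pixelSize(movie)
  dt <- frameInterval(movie)
  r_px <- (cfg@blobDiameterUm / 2) / px
  out <- list()
  for (f in seq_len(dim(stack)[3])) {
    img <- stack[, , f]
    resp <- dogResponse(img, cfg@blobDiameterUm, px, cfg@dogSigmaRatio)
    cand <- .localMaxima(resp, img, r_px, cfg@qualityMin)
    if (!nrow(cand)) next
    sub <- .subpixelRefine(resp, cand, cfg@subpixel)
    inten <- .spotPhotometry(img, cand, r_px)
    out[[length(out) + 1L]] <- data.frame(
      frame = f, t_s = (f - 1) * dt,
      x_um = (cand$col - 1 + 0.5 + sub$dx) * px,
      y_um = (cand$row - 1 + 0.5 + sub$dy) * px,
      quality = cand$q, intensity = inten)
  }
  if (!length(out))
    return(data.frame(id = integer(), frame = integer(), t_s = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      quality = numeric(), intensity = numeric()))
  spots <- do.call(rbind, out)
  if (cfg@useAutoThreshold && nrow(spots) >= 2L) {
    thr <- autoQualityThreshold(spots$quality)
    spots <- spots[spots$quality >= thr, , drop = FALSE]
  }
  spots <- spots[order(spots$frame, -spots$quality), , drop = FALSE]
  spots$id <- seq_len(nrow(spots))
  rownames(spots) <- NULL
  spots[, c("id", "frame", "t_s", "x_um", "y_um", "quality", "intensity")]
}

## local maxima of resp with greedy NMS at radius r_px; returns row/col/q
.localMaxima <- function(resp, img, r_px, qmin) {
  H <- nrow(resp); W <- ncol(resp)
  ## strict 3x3 maxima above threshold (border excluded)
  c0 <- resp[2:(H - 1), 2:(W - 1)]
  is_max <- c0 >= qmin
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (c0 >= resp[2:(H - 1) + dr, 2:(W - 1) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(row = integer(), col = integer(), q = numeric()))
  rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L
  q <- resp[cbind(rows, cols)]
  raw <- img[cbind(rows, cols)]
  o <- order(-q, -raw, rows, cols)
  rows <- rows[o]; cols <- cols[o]; q <- q[o]
  keep <- logical(length(q))
  kr <- numeric(0); kc <- numeric(0)
  r2 <- r_px^2
  for (i in seq_along(q)) {
    if (!length(kr) || all((kr - rows[i])^2 + (kc - cols[i])^2 > r2)) {
      keep[i] <- TRUE
      kr <- c(kr, rows[i]); kc <- c(kc, cols[i])
    }
  }
  data.frame(row = rows[keep], col = cols[keep], q = q[keep])
}

## quadratic 3x3 sub-pixel refinement, offsets clamped to [-0.5, 0.5]
.subpixelRefine <- function(resp, cand, enabled) {
  n <- nrow(cand)
  dx <- numeric(n); dy <- numeric(n)
  if (!enabled || !n) return(list(dx = dx, dy = dy))
  H <- nrow(resp); W <- ncol(resp)
  for (i in seq_len(n)) {
    r <- cand$row[i]; c <- cand$col[i]
    if (r <= 1L || r >= H || c <= 1L || c >= W) next
    den_x <- resp[r, c - 1] - 2 * resp[r, c] + resp[r, c + 1]
    den_y <- resp[r - 1, c] - 2 * resp[r, c] + resp[r + 1, c]
    if (den_x < 0) dx[i] <- 0.5 * (resp[r, c - 1] - resp[r, c + 1]) / den_x
    if (den_y < 0) dy[i] <- 0.5 * (resp[r - 1, c] - resp[r + 1, c]) / den_y
    dx[i] <- max(-0.5, min(0.5, dx[i]))
    dy[i] <- max(-0.5, min(0.5, dy[i]))
  }
  list(dx = dx, dy = dy)
}

## summed disk intensity minus local median annulus background
.spotPhotometry <- function(img, cand, r_px) {
  H <- nrow(img); W <- ncol(img)
  w <- ceiling(2.5 * r_px)
  vapply(seq_len(nrow(cand)), function(i) {
    r <- cand$row[i]; c <- cand$col[i]
    rr <- max(1L, r - w):min(H, r + w)
    cc <- max(1L, c - w):min(W, c + w)
    d2 <- outer((rr - r)^2, (cc - c)^2, "+")
    patch <- img[rr, cc, drop = FALSE]
    disk <- d2 <= r_px^2
    ann <- d2 >= (1.5 * r_px)^2 & d2 <= (2.5 * r_px)^2
    bg <- if (any(ann)) stats::median(patch[ann]) else 0
    sum(patch[disk]) - bg * sum(disk)
  }, numeric(1))
}
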