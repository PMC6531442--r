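## Cortical-actin clearance quantification: percentile thresholding,
## connected-component morphometry with area/circularity filters,
## granule-actin contact, cortex vs cytoplasm intensity, line profiles.

#' Percentile auto-threshold segmentation of dark regions
#'
#' Doyle's percentile auto-threshold on a 256-bin histogram: the threshold
#' is placed where the cumulative pixel fraction is closest to
#' `targetFraction` (default 0.5). With `darkBackground = FALSE` (the
#' convention for bright actin on dark clearances) pixels below the
#' threshold form the foreground mask; with `darkBackground = TRUE` the
#' rule is applied symmetrically to the inverted image, so inverting the
#' image and toggling the flag yields the identical mask.
#'
#' @param image numeric matrix.
#' @param targetFraction target foreground fraction, default 0.5.
#' @param darkBackground when TRUE, bright pixels form the foreground.
#' @param nbins histogram bins.
#' @return logical mask with attribute `threshold`. A constant image
#'   yields an empty mask with a warning.
#' @export
percentileThreshold <- function(image, targetFraction = 0.5,
                                darkBackground = FALSE, nbins = 256L) {
  if (!is.matrix(image)) image <- as.matrix(image)
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("constant image: no threshold exists; returning empty mask")
    m <- matrix(FALSE, nrow(image), ncol(image))
    attr(m, "threshold") <- rng[1]
    return(m)
  }
  if (darkBackground) {
    ## symmetric rule: bright foreground = dark foreground of the inverted image
    inv <- rng[1] + rng[2] - image
    m <- percentileThreshold(inv, targetFraction, FALSE, nbins)
    attr(m, "threshold") <- rng[1] + rng[2] - attr(m, "threshold")
    return(m)
  }
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(pmin(nbins, findInterval(image, breaks, rightmost.closed = TRUE)),
                nbins)
  cum <- cumsum(h) / sum(h)
  k <- which.min(abs(cum - targetFraction))
  thr <- breaks[k + 1L]
  m <- image < thr
  if (k == nbins) m[image == thr] <- TRUE  # whole range selected
  attr(m, "threshold") <- thr
  m
}

## connected-component labeling; EBImage::bwlabel is 4-connected, the
## 8-connected variant merges labels that touch diagonally (union-find).
.labelMask <- function(mask, connectivity = 8L) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  nl <- max(lab)
  parent <- seq_len(nl)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unionp <- function(i, j) { ri <- findp(i); rj <- findp(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  a <- lab[1:(H - 1), 1:(W - 1)]; b <- lab[2:H, 2:W]
  idx <- which(a > 0 & b > 0 & a != b)
  if (length(idx)) for (i in idx) unionp(a[i], b[i])
  a <- lab[1:(H - 1), 2:W]; b <- lab[2:H, 1:(W - 1)]
  idx <- which(a > 0 & b > 0 & a != b)
  if (length(idx)) for (i in idx) unionp(a[i], b[i])
  roots <- vapply(seq_len(nl), findp, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

## Moore boundary tracing; perimeter = chain length with sqrt(2) diagonals.
## Single-pixel regions get the 4-sided outline perimeter.
.chainPerimeter <- function(region_mask) {
  idx <- which(region_mask, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(4)
  ## pad to avoid border checks
  H <- nrow(region_mask); W <- ncol(region_mask)
  m <- matrix(FALSE, H + 2L, W + 2L)
  m[2:(H + 1L), 2:(W + 1L)] <- region_mask
  ## start: topmost of leftmost column containing the region
  idx <- which(m, arr.ind = TRUE)
  start <- idx[order(idx[, 2], idx[, 1])[1], ]
  ## Moore neighborhood clockwise starting from W
  nb <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
              c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  steplen <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  cur <- start
  backtrack <- 1L  # came from the west
  per <- 0
  first_next <- NULL
  prev <- cur
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((backtrack - 1L + k) %% 8L) + 1L
      cand <- cur + nb[d, ]
      if (m[cand[1], cand[2]]) {
        ## Jacob's stopping criterion: about to repeat the first move
        if (!is.null(first_next) && all(cur == start) && all(cand == first_next)) {
          return(per)
        }
        per <- per + steplen[d]
        ## next scan starts one step clockwise of the direction back to prev
        backtrack <- ((d + 4L) %% 8L) + 1L
        prev <- cur
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) return(4)  # isolated pixel (no traceable neighbors)
    if (is.null(first_next)) first_next <- cur
    if (per > 8 * (H + W)) break  # safety
  }
  per
}

#' Circularity of a region
#'
#' 4 * pi * area / perimeter^2, clamped at 1 (as ImageJ does for digital
#' regions whose estimated perimeter is slightly short).
#'
#' @param area region area.
#' @param perimeter region perimeter (same length unit).
#' @return circularity in (0, 1].
#' @examples
#' circularity(1, 4)  # unit square: pi/4
#' @export
circularity <- function(area, perimeter) {
  pmin(1, 4 * pi * area / perimeter^2)
}

#' Find actin clearances in a binary mask
#'
#' Connected components of the dark-region mask are measured (area in
#' um^2, perimeter by Moore boundary tracing with sqrt(2)-weighted
#' diagonal steps, circularity 4*pi*A/P^2 clamped at 1, centroid,
#' eccentricity from second moments) and filtered by the configured area
#' and circularity bounds; border-touching regions are discarded when
#' `cfg@excludeBorder` is on.
#'
#' @param mask logical matrix of candidate clearance pixels.
#' @param pixelSizeUm pixel size (um).
#' @param cfg a [ClearanceConfig-class].
#' @return data.frame with `label`, `area_um2`, `perimeter_um`,
#'   `circularity`, `x_um`, `y_um`, `eccentricity`.
#' @export
findClearances <- function(mask, pixelSizeUm, cfg = clearanceConfig()) {
  stopifnot(is(cfg, "ClearanceConfig"))
  if (!any(mask)) return(.emptyRegions())
  lab <- .labelMask(mask, cfg@connectivity)
  nl <- max(lab)
  H <- nrow(mask); W <- ncol(mask)
  rows <- list()
  for (l in seq_len(nl)) {
    rm <- lab == l
    npx <- sum(rm)
    idx <- which(rm, arr.ind = TRUE)
    touches <- any(idx[, 1] == 1L | idx[, 1] == H | idx[, 2] == 1L | idx[, 2] == W)
    if (cfg@excludeBorder && touches) next
    area <- npx * pixelSizeUm^2
    if (area < cfg@areaMinUm2 || area > cfg@areaMaxUm2) next
    per <- .chainPerimeter(rm) * pixelSizeUm
    circ <- circularity(area, per)
    if (circ < cfg@circMin || circ > cfg@circMax) next
    cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
    mu20 <- mean((idx[, 2] - cx)^2); mu02 <- mean((idx[, 1] - cy)^2)
    mu11 <- mean((idx[, 2] - cx) * (idx[, 1] - cy))
    tr <- mu20 + mu02
    dlt <- sqrt(pmax(0, (mu20 - mu02)^2 + 4 * mu11^2))
    l1 <- (tr + dlt) / 2; l2 <- (tr - dlt) / 2
    ecc <- if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      label = l, area_um2 = area, perimeter_um = per, circularity = circ,
      x_um = (cx - 0.5) * pixelSizeUm, y_um = (cy - 0.5) * pixelSizeUm,
      eccentricity = ecc)
  }
  if (!length(rows)) return(.emptyRegions())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.emptyRegions <- function() {
  data.frame(label = integer(), area_um2 = numeric(), perimeter_um = numeric(),
             circularity = numeric(), x_um = numeric(), y_um = numeric(),
             eccentricity = numeric())
}

#' Clearance frequency per square micron
#'
#' @param regions data.frame from [findClearances()] (or any table with
#'   one row per clearance).
#' @param analyzedAreaUm2 analyzed cortical area (um^2), > 0.
#' @return clearances per um^2.
#' @examples
#' clearanceFrequency(data.frame(label = 1:5), 100)
#' @export
clearanceFrequency <- function(regions, analyzedAreaUm2) {
  if (analyzedAreaUm2 <= 0) stop("analyzed area must be > 0")
  nrow(regions) / analyzedAreaUm2
}

#' Granule-actin contact flags
#'
#' A spot is "in contact" with the actin meshwork when any pixel whose
#' center lies within `radiusUm` of the spot position exceeds the contact
#' threshold. The threshold is either absolute (`threshold`) or a
#' quantile of the actin image (`thresholdQuantile`, default the 75th
#' percentile). This is an explicit operationalization of a contact
#' measurement that can be validated on planted geometry.
#'
#' @param spots data.frame with `x_um`, `y_um`.
#' @param actinImage numeric matrix.
#' @param pixelSizeUm pixel size (um).
#' @param radiusUm contact radius (um), default 0.3 (the blob radius).
#' @param threshold absolute intensity threshold; overrides the quantile.
#' @param thresholdQuantile quantile of `actinImage` used when `threshold`
#'   is NULL.
#' @return logical vector, one flag per spot.
#' @export
actinContact <- function(spots, actinImage, pixelSizeUm, radiusUm = 0.3,
                         threshold = NULL, thresholdQuantile = 0.75) {
  if (radiusUm < pixelSizeUm) stop("contact radius below one pixel")
  thr <- if (is.null(threshold))
    stats::quantile(actinImage, thresholdQuantile, names = FALSE)
  else threshold
  H <- nrow(actinImage); W <- ncol(actinImage)
  r_px <- radiusUm / pixelSizeUm
  w <- ceiling(r_px)
  vapply(seq_len(nrow(spots)), function(i) {
    cc <- spots$x_um[i] / pixelSizeUm + 0.5
    cr <- spots$y_um[i] / pixelSizeUm + 0.5
    rr <- max(1L, floor(cr - w)):min(H, ceiling(cr + w))
    ccs <- max(1L, floor(cc - w)):min(W, ceiling(cc + w))
    d2 <- outer((rr - cr)^2, (ccs - cc)^2, "+")
    any(actinImage[rr, ccs, drop = FALSE][d2 <= r_px^2] > thr)
  }, logical(1))
}

#' Cortical versus cytoplasmic mean intensity
#'
#' Splits a filled cell mask into a cortical shell (pixels within
#' `shellWidthUm` of the mask boundary, obtained by erosion with a disc)
#' and the remaining interior, and returns the mean intensity of each.
#'
#' @param image numeric matrix.
#' @param cellMask logical matrix (filled cell region).
#' @param pixelSizeUm pixel size (um).
#' @param shellWidthUm cortical shell width (um), default 1.0.
#' @return list with `cortex_mean` and `cytoplasm_mean`.
#' @export
cortexVsCytoplasmIntensity <- function(image, cellMask, pixelSizeUm,
                                       shellWidthUm = 1.0) {
  if (shellWidthUm <= 0) stop("shell width must be > 0")
  if (!any(cellMask)) stop("empty cell mask")
  r_px <- max(1L, round(shellWidthUm / pixelSizeUm))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  interior <- EBImage::imageData(EBImage::erode(cellMask * 1, brush)) > 0
  if (!any(interior)) stop("cortical shell consumes the whole mask")
  shell <- cellMask & !interior
  list(cortex_mean = mean(image[shell]), cytoplasm_mean = mean(image[interior]))
}

#' Intensity profile along a line segment
#'
#' Samples the image by bilinear interpolation at unit-pixel spacing along
#' the segment from `p0` to `p1` (positions in um), averaging across
#' `widthPx` parallel lines spaced one pixel apart.
#'
#' @param image numeric matrix.
#' @param p0,p1 numeric (x_um, y_um) endpoints inside the image.
#' @param pixelSizeUm pixel size (um).
#' @param widthPx averaging width in pixels (odd integer), default 1.
#' @return data.frame with `distance_um` and `intensity`.
#' @export
lineProfile <- function(image, p0, p1, pixelSizeUm, widthPx = 1L) {
  v <- c(p1[1] - p0[1], p1[2] - p0[2])
  len <- sqrt(sum(v^2))
  if (len == 0) stop("zero-length segment")
  u <- v / len
  nrm <- c(-u[2], u[1])
  ns <- floor(len / pixelSizeUm) + 1L
  s <- seq(0, by = pixelSizeUm, length.out = ns)
  offs <- (seq_len(widthPx) - (widthPx + 1) / 2) * pixelSizeUm
  prof <- rowMeans(vapply(offs, function(o) {
    xs <- p0[1] + s * u[1] + o * nrm[1]
    ys <- p0[2] + s * u[2] + o * nrm[2]
    .bilinear(image, xs / pixelSizeUm + 0.5, ys / pixelSizeUm + 0.5)
  }, numeric(ns)))
  data.frame(distance_um = s, intensity = prof)
}

## bilinear interpolation at fractional (col, row) pixel-center coordinates
.bilinear <- function(img, cc, rr) {
  H <- nrow(img); W <- ncol(img)
  cc <- pmin(pmax(cc, 1), W)
  rr <- pmin(pmax(rr, 1), H)
  c0 <- pmin(floor(cc), W - 1L); r0 <- pmin(floor(rr), H - 1L)
  fc <- cc - c0; fr <- rr - r0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}
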