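## Two-phase LAP particle linking: frame-to-frame linking, then gap closing.
##
## Both phases solve a rectangular assignment augmented with per-particle
## "no-link" alternatives in the classic LAP-tracker layout: for n sources
## and m targets a (n + m) square cost matrix holds squared distances for
## admissible pairs in the top-left block, the alternative cost
## b = alternativeCostFactor * maxDist^2 on the diagonals of the top-right
## and bottom-left blocks, and zeros in the bottom-right completion block.
## Minimizing total cost then maximizes the number of admissible links and
## picks the minimum total squared displacement among them.

.BIG <- 1e9

## solve the padded LAP; returns integer vector: for each source 1..n the
## matched target index, or NA when unlinked. dist2 is n x m with Inf for
## inadmissible pairs.
.lapLink <- function(dist2, alt_cost) {
  n <- nrow(dist2); m <- ncol(dist2)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  sz <- n + m
  cost <- matrix(.BIG, sz, sz)
  tl <- dist2
  tl[!is.finite(tl)] <- .BIG
  cost[1:n, 1:m] <- tl
  cost[cbind(1:n, m + 1:n)] <- alt_cost
  cost[cbind(n + 1:m, 1:m)] <- alt_cost
  cost[n + 1:m, m + 1:n] <- 0
  sol <- as.integer(clue::solve_LSAP(cost))
  match <- sol[1:n]
  ifelse(match <= m & is.finite(dist2[cbind(1:n, pmin(match, m))]), match, NA_integer_)
}

#' Link spots between consecutive frames into track fragments
#'
#' For every consecutive frame pair, solves a linear assignment with cost
#' equal to squared Euclidean distance for spot pairs closer than
#' `maxLinkDistUm`, with per-spot no-link alternatives priced at
#' `alternativeCostFactor * maxLinkDistUm^2`. Fragments are maximal chains
#' of links.
#'
#' @param spots data.frame with `id`, `frame`, `x_um`, `y_um` (unique ids).
#' @param cfg a [LinkingConfig-class].
#' @return list of integer vectors, each the frame-ordered spot ids of one
#'   fragment (singletons included).
#' @export
linkFrames <- function(spots, cfg = linkingConfig()) {
  stopifnot(is(cfg, "LinkingConfig"))
  if (!nrow(spots)) return(list())
  if (anyDuplicated(spots$id)) stop("duplicate spot ids")
  spots <- spots[order(spots$frame, spots$x_um, spots$y_um), , drop = FALSE]
  byf <- split(seq_len(nrow(spots)), spots$frame)
  fr <- as.integer(names(byf))
  nxt <- rep(NA_integer_, nrow(spots))   # row index of linked spot in next frame
  dmax2 <- cfg@maxLinkDistUm^2
  for (k in seq_len(length(fr) - 1L)) {
    if (fr[k + 1L] != fr[k] + 1L) next   # only consecutive frame indices
    a <- byf[[k]]; b <- byf[[k + 1L]]
    d2 <- outer(spots$x_um[a], spots$x_um[b], "-")^2 +
          outer(spots$y_um[a], spots$y_um[b], "-")^2
    d2[d2 > dmax2] <- Inf
    match <- .lapLink(d2, cfg@alternativeCostFactor * dmax2)
    ok <- !is.na(match)
    nxt[a[ok]] <- b[match[ok]]
  }
  ## maximal chains
  has_prev <- logical(nrow(spots))
  has_prev[nxt[!is.na(nxt)]] <- TRUE
  frags <- list()
  for (s in which(!has_prev)) {
    chain <- s
    while (!is.na(nxt[chain[length(chain)]])) chain <- c(chain, nxt[chain[length(chain)]])
    frags[[length(frags) + 1L]] <- spots$id[chain]
  }
  frags
}

#' Close gaps between track fragments
#'
#' Solves one assignment between fragment ends and fragment starts. A pair
#' (end, start) is admissible when the start follows the end by at least
#' one and at most `maxFrameGap` frames (under the `"frame_difference"`
#' convention; `"missing_frames"` allows one frame more) and lies within
#' `maxGapDistUm`. Accepted bridges merge fragments; every bridge is
#' recorded as a closed gap span.
#'
#' @param fragments list of spot-id vectors from [linkFrames()].
#' @param spots the spot table the fragments index into.
#' @param cfg a [LinkingConfig-class].
#' @return a [TrackSet-class].
#' @export
closeGaps <- function(fragments, spots, cfg = linkingConfig()) {
  stopifnot(is(cfg, "LinkingConfig"))
  ids <- unlist(fragments)
  if (anyDuplicated(ids)) stop("fragments overlap in spot identity")
  rowOf <- match(ids, spots$id)
  if (anyNA(rowOf)) stop("fragment spot id missing from spot table")

  nf <- length(fragments)
  nxt_frag <- rep(NA_integer_, nf)
  bridges <- data.frame(from = integer(), to = integer(),
                        frame_before = integer(), frame_after = integer())
  maxgap <- cfg@maxFrameGap +
    if (cfg@gapConvention == "missing_frames") 1L else 0L
  if (nf > 1L && cfg@maxFrameGap > 0L) {
    endRow <- vapply(fragments, function(f) match(f[length(f)], spots$id), integer(1))
    staRow <- vapply(fragments, function(f) match(f[1L], spots$id), integer(1))
    dgap <- outer(spots$frame[staRow], spots$frame[endRow], "-")  # [start, end]
    d2 <- outer(spots$x_um[staRow], spots$x_um[endRow], "-")^2 +
          outer(spots$y_um[staRow], spots$y_um[endRow], "-")^2
    adm <- t(dgap) >= 1 & t(dgap) <= maxgap & t(d2) <= cfg@maxGapDistUm^2
    d2 <- t(d2)
    d2[!adm] <- Inf
    if (any(adm)) {
      match <- .lapLink(d2, cfg@alternativeCostFactor * cfg@maxGapDistUm^2)
      for (p in which(!is.na(match))) {
        q <- match[p]
        nxt_frag[p] <- q
        bridges <- rbind(bridges, data.frame(
          from = p, to = q,
          frame_before = spots$frame[endRow[p]],
          frame_after = spots$frame[staRow[q]]))
      }
    }
  }

  ## walk merged chains into tracks
  has_prev <- logical(nf)
  has_prev[nxt_frag[!is.na(nxt_frag)]] <- TRUE
  trk_spots <- list(); trk_gaps <- list()
  for (p0 in which(!has_prev)) {
    chain <- p0
    while (!is.na(nxt_frag[chain[length(chain)]]))
      chain <- c(chain, nxt_frag[chain[length(chain)]])
    sid <- unlist(fragments[chain])
    trk_spots[[length(trk_spots) + 1L]] <- sid
    g <- bridges[bridges$from %in% chain, c("frame_before", "frame_after"), drop = FALSE]
    trk_gaps[[length(trk_gaps) + 1L]] <- g
  }

  ## deterministic track ids by (first frame, x, y) of the first spot
  first <- vapply(trk_spots, function(s) match(s[1L], spots$id), integer(1))
  o <- order(spots$frame[first], spots$x_um[first], spots$y_um[first])
  trk_spots <- trk_spots[o]; trk_gaps <- trk_gaps[o]

  sp <- do.call(rbind, lapply(seq_along(trk_spots), function(i) {
    d <- spots[match(trk_spots[[i]], spots$id), , drop = FALSE]
    d$track_id <- i
    d
  }))
  gp <- do.call(rbind, lapply(seq_along(trk_gaps), function(i) {
    g <- trk_gaps[[i]]
    if (is.null(g) || !nrow(g))
      data.frame(track_id = integer(), frame_before = integer(), frame_after = integer())
    else
      data.frame(track_id = i, frame_before = g$frame_before, frame_after = g$frame_after)
  }))
  if (is.null(sp)) sp <- data.frame(track_id = integer(), id = integer(),
                                    frame = integer(), x_um = numeric(), y_um = numeric())
  rownames(sp) <- NULL
  new("TrackSet", spots = sp, gaps = gp, config = cfg)
}

#' Track spots: linking plus gap closing
#'
#' Composition of [linkFrames()] and [closeGaps()]; track ids are assigned
#' deterministically by the (first frame, x, y) of each track's first spot.
#'
#' @param spots spot data.frame (see [linkFrames()]).
#' @param cfg a [LinkingConfig-class].
#' @return a [TrackSet-class].
#' @examples
#' sp <- data.frame(id = 1:4, frame = c(1, 1, 2, 2),
#'                  x_um = c(0, 3, 0.2, 3.1), y_um = c(0, 0, 0, 0.1))
#' nTracks(trackSpots(sp))
#' @export
trackSpots <- function(spots, cfg = linkingConfig()) {
  if (!nrow(spots))
    return(new("TrackSet",
               spots = data.frame(track_id = integer(), id = integer(),
                                  frame = integer(), x_um = numeric(), y_um = numeric()),
               gaps = data.frame(track_id = integer(), frame_before = integer(),
                                 frame_after = integer()),
               config = cfg))
  closeGaps(linkFrames(spots, cfg), spots, cfg)
}
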