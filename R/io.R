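## Readers and writers: TrackMate XML, multi-page TIFF with JSON sidecar
## calibration, CSV tables, YAML pipeline configuration.

#' Import a TrackMate model XML file
#'
#' Reads spots from `<AllSpots>`, edges from `<AllTracks>` and the track
#' filter from `<FilteredTracks>` (when present, only listed tracks are
#' kept). Positions are converted to micrometers: files with spatial
#' units of pixels require `pixelSizeUm`. Track ids are reassigned
#' deterministically by (first frame, x, y) of each track's first spot.
#'
#' @param path path to a TrackMate XML file.
#' @param pixelSizeUm pixel size (um), required only when the file's
#'   spatial units are pixels.
#' @param frameIntervalS frame interval used to fill `t_s` when the file
#'   carries no `POSITION_T`; default 1.
#' @return list with `spots` (data.frame of all imported spots),
#'   `trackset` (a [TrackSet-class] of the filtered tracks) and
#'   `calibration` (list with the file's spatial units).
#' @export
readTrackMateXML <- function(path, pixelSizeUm = NULL, frameIntervalS = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  model <- if (xml2::xml_name(doc) == "Model") doc
           else xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing")) stop("no <Model> element in ", path)
  units <- xml2::xml_attr(model, "spatialunits")
  scale <- 1
  if (!is.na(units) && grepl("pixel", units, ignore.case = TRUE)) {
    if (is.null(pixelSizeUm))
      stop("file positions are in pixels; supply pixelSizeUm")
    scale <- pixelSizeUm
  }

  spot_nodes <- xml2::xml_find_all(model, ".//AllSpots//Spot")
  need <- c("ID", "POSITION_X", "POSITION_Y", "FRAME")
  getAttr <- function(nodes, what, required = TRUE) {
    v <- xml2::xml_attr(nodes, what)
    if (required && anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("missing attribute ", what, " at ", xml2::xml_path(nodes[[bad]]))
    }
    v
  }
  if (length(spot_nodes)) {
    for (a in need) getAttr(spot_nodes, a)
    tt <- suppressWarnings(as.numeric(xml2::xml_attr(spot_nodes, "POSITION_T")))
    fr <- as.integer(as.numeric(getAttr(spot_nodes, "FRAME")))
    spots <- data.frame(
      id = as.integer(as.numeric(getAttr(spot_nodes, "ID"))),
      frame = fr,
      t_s = ifelse(is.na(tt), fr * frameIntervalS, tt),
      x_um = as.numeric(getAttr(spot_nodes, "POSITION_X")) * scale,
      y_um = as.numeric(getAttr(spot_nodes, "POSITION_Y")) * scale,
      quality = suppressWarnings(as.numeric(xml2::xml_attr(spot_nodes, "QUALITY"))),
      intensity = suppressWarnings(as.numeric(xml2::xml_attr(spot_nodes, "TOTAL_INTENSITY"))))
  } else {
    spots <- data.frame(id = integer(), frame = integer(), t_s = numeric(),
                        x_um = numeric(), y_um = numeric(),
                        quality = numeric(), intensity = numeric())
  }

  track_nodes <- xml2::xml_find_all(model, ".//AllTracks/Track")
  filt <- xml2::xml_find_all(model, ".//FilteredTracks/TrackID")
  keep_ids <- if (length(filt))
    as.integer(as.numeric(getAttr(filt, "TRACK_ID"))) else NULL

  members <- list()
  for (tn in track_nodes) {
    tid <- as.integer(as.numeric(xml2::xml_attr(tn, "TRACK_ID")))
    if (is.na(tid)) stop("missing TRACK_ID at ", xml2::xml_path(tn))
    if (!is.null(keep_ids) && !tid %in% keep_ids) next
    edges <- xml2::xml_find_all(tn, ".//Edge")
    if (!length(edges)) next
    src <- as.integer(as.numeric(getAttr(edges, "SPOT_SOURCE_ID")))
    dst <- as.integer(as.numeric(getAttr(edges, "SPOT_TARGET_ID")))
    members[[length(members) + 1L]] <- unique(c(src, dst))
  }

  sp <- do.call(rbind, lapply(members, function(ids) {
    d <- spots[match(ids, spots$id), , drop = FALSE]
    if (anyNA(d$id)) stop("track references unknown spot id")
    d[order(d$frame), , drop = FALSE]
  }))
  ts <- if (is.null(sp) || !nrow(sp)) {
    trackSpots(data.frame(id = integer(), frame = integer(),
                          x_um = numeric(), y_um = numeric()))
  } else {
    ## deterministic order: first frame, then x, then y of the first spot
    key <- t(vapply(members, function(ids) {
      d <- spots[match(ids, spots$id), ]
      d <- d[order(d$frame), ]
      c(d$frame[1], d$x_um[1], d$y_um[1])
    }, numeric(3)))
    o <- order(key[, 1], key[, 2], key[, 3])
    sp2 <- do.call(rbind, lapply(seq_along(o), function(i) {
      ids <- members[[o[i]]]
      d <- spots[match(ids, spots$id), , drop = FALSE]
      d <- d[order(d$frame), , drop = FALSE]
      d$track_id <- i
      d
    }))
    gaps <- do.call(rbind, lapply(split(sp2, sp2$track_id), function(d) {
      j <- which(diff(d$frame) > 1L)
      if (!length(j)) return(NULL)
      data.frame(track_id = d$track_id[1],
                 frame_before = d$frame[j], frame_after = d$frame[j + 1L])
    }))
    if (is.null(gaps))
      gaps <- data.frame(track_id = integer(), frame_before = integer(),
                         frame_after = integer())
    rownames(sp2) <- NULL
    new("TrackSet", spots = sp2, gaps = gaps, config = linkingConfig())
  }
  list(spots = spots, trackset = ts,
       calibration = list(spatialunits = units, scale = scale))
}

## ---------------------------------------------------------------------------
## TIFF round trip
## ---------------------------------------------------------------------------

#' Write a movie as multi-page TIFF with a JSON calibration sidecar
#'
#' Pixel counts are stored as 16-bit samples (values are divided by
#' 65535, so integer stacks up to 65535 round-trip bit-exactly); the
#' calibration (pixel size, frame interval, scale) goes to `<path>.json`.
#'
#' @param movie a [TirfMovie-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeMovieTIFF <- function(movie, path) {
  stopifnot(is(movie, "TirfMovie"))
  stack <- frames(movie)
  if (max(stack) > 65535) {
    warning("pixel values above 65535 clipped for 16-bit storage")
    stack <- pmin(stack, 65535)
  }
  if (min(stack) < 0) stop("negative pixel values cannot be stored")
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = pixelSize(movie), frame_interval_s = frameInterval(movie),
         scale = 65535),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' Calibration is taken from the JSON sidecar written by
#' [writeMovieTIFF()] when present, otherwise from the arguments.
#'
#' @param path TIFF path.
#' @param pixelSizeUm,frameIntervalS calibration used when no sidecar
#'   exists.
#' @return a [TirfMovie-class].
#' @export
readMovieTIFF <- function(path, pixelSizeUm = NULL, frameIntervalS = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- paste0(path, ".json")
  scale <- 65535
  if (file.exists(side)) {
    cal <- jsonlite::read_json(side, simplifyVector = TRUE)
    pixelSizeUm <- cal$pixel_size_um
    frameIntervalS <- cal$frame_interval_s
    scale <- cal$scale
  }
  if (is.null(pixelSizeUm) || is.null(frameIntervalS))
    stop("no calibration sidecar; supply pixelSizeUm and frameIntervalS")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) stack[, , k] <- round(pages[[k]] * scale)
  tirfMovie(stack, pixelSizeUm, frameIntervalS)
}

## ---------------------------------------------------------------------------
## CSV tables
## ---------------------------------------------------------------------------

#' Write and read analysis tables as CSV
#'
#' Plain UTF-8 comma-separated files with a mandatory header row and '.'
#' as the decimal mark; numeric columns survive a round trip at full
#' double precision.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeTableCSV <- function(x, path) {
  utils::write.csv(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTableCSV
#' @export
readTableCSV <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, header = TRUE)
}

#' Write ground truth as CSV
#'
#' One row per particle per frame: `particle_id`, `frame`, `x_um`,
#' `y_um`, `intensity`, `label`, `visible` (plus `t_s`, `z_um`, `in_fov`).
#'
#' @param truth a [GroundTruth-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeGroundTruthCSV <- function(truth, path) {
  d <- truthTable(truth)
  writeTableCSV(d[, c("particle_id", "frame", "t_s", "x_um", "y_um", "z_um",
                      "intensity", "label", "in_fov", "visible")], path)
}

## ---------------------------------------------------------------------------
## Pipeline configuration (YAML)
## ---------------------------------------------------------------------------

.s4ToList <- function(obj) {
  out <- lapply(methods::slotNames(obj), function(s) methods::slot(obj, s))
  names(out) <- methods::slotNames(obj)
  out
}

#' Assemble a pipeline configuration
#'
#' Bundles every stage configuration plus the seed and output directory.
#' `behaviors` drive the synthetic-movie stage; `cortex` the clearance
#' stage. Any component may be omitted to use defaults.
#'
#' @param optics an [OpticsConfig-class] or a preset name.
#' @param behaviors list of [BehaviorSpec-class].
#' @param detection a [DetectionConfig-class].
#' @param linking a [LinkingConfig-class].
#' @param profile a [ProfileCriteria-class].
#' @param duration a [DurationThresholds-class].
#' @param clearance a [ClearanceConfig-class].
#' @param cortex a [cortexSimSpec()] list.
#' @param seed integer master seed.
#' @param outputDir output directory.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(optics = opticsPreset("TIRFM"),
                           behaviors = list(behaviorSpec("stationary", 3, jitterSdUm = 0.02)),
                           detection = detectionConfig(),
                           linking = linkingConfig(),
                           profile = profileCriteria(),
                           duration = durationThresholds(),
                           clearance = clearanceConfig(),
                           cortex = cortexSimSpec(),
                           seed = 1L, outputDir = "cg-output") {
  if (is.character(optics)) optics <- opticsPreset(optics)
  cfg <- list(optics = optics, behaviors = behaviors, detection = detection,
              linking = linking, profile = profile, duration = duration,
              clearance = clearance, cortex = cortex,
              seed = as.integer(seed), outputDir = outputDir)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Serialize / parse a pipeline configuration as YAML
#'
#' `writePipelineConfig()` followed by `readPipelineConfig()` reproduces
#' an equal configuration (round-trip property).
#'
#' @param cfg a [pipelineConfig()] object.
#' @param path YAML file path.
#' @return the path (write) or a `PipelineConfig` (read).
#' @export
writePipelineConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  y <- list(
    optics = .s4ToList(cfg$optics),
    behaviors = lapply(cfg$behaviors, .s4ToList),
    detection = .s4ToList(cfg$detection),
    linking = .s4ToList(cfg$linking),
    profile = .s4ToList(cfg$profile),
    duration = .s4ToList(cfg$duration),
    clearance = .s4ToList(cfg$clearance),
    cortex = unclass(cfg$cortex),
    seed = cfg$seed, outputDir = cfg$outputDir)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  mk <- function(ctor, lst) do.call(ctor, lst)
  beh <- lapply(y$behaviors, function(b)
    behaviorSpec(label = b$label, nParticles = b$nParticles,
                 diffusionCoeffUm2S = b$diffusionCoeffUm2S %||% 0,
                 speedUmS = b$speedUmS %||% 0,
                 jitterSdUm = b$jitterSdUm %||% 0,
                 zStartUm = b$zStartUm %||% 0, zRateUmS = b$zRateUmS %||% 0,
                 birthFrame = b$birthFrameRange %||% 1L,
                 deathFrame = b$deathFrameRange %||% -1L,
                 intensity = b$intensity %||% 1,
                 rampRate = b$rampRate %||% 0,
                 missProb = b$missProb %||% 0))
  cz <- y$cortex
  cz$clearanceAxesUm <- if (!is.null(cz$clearanceAxesUm))
    matrix(unlist(cz$clearanceAxesUm), ncol = 2) else NULL
  pipelineConfig(
    optics = mk(opticsConfig, y$optics),
    behaviors = beh,
    detection = mk(detectionConfig, y$detection),
    linking = mk(linkingConfig, y$linking),
    profile = mk(profileCriteria, y$profile),
    duration = mk(durationThresholds, y$duration),
    clearance = mk(clearanceConfig, y$clearance),
    cortex = do.call(cortexSimSpec, cz[!vapply(cz, is.null, logical(1))]),
    seed = y$seed, outputDir = y$outputDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
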