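## Diagnostic figure suite for the track-feature table.

#' Standard figure suite for track features
#'
#' Writes five figures into `dir`: a histogram of track durations, a
#' 2D density (hexbin) plot of duration against track start time, violin
#' plots of mean track intensity by duration class, stacked
#' class-proportion bars (profile class within duration class), and an
#' overlay of tracks colored by time on the movie's first frame (or on an
#' empty canvas when no movie is supplied). File names are deterministic.
#'
#' @param features data.frame from [trackFeatures()].
#' @param dir output directory (created if missing).
#' @param trackset optional [TrackSet-class] for the overlay panel.
#' @param movie optional [TirfMovie-class]; its first frame backs the overlay.
#' @return character vector of the five file paths, invisibly.
#' @export
plotSuite <- function(features, dir, trackset = NULL, movie = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("duration_histogram.png", "start_time_hexbin.png",
                            "intensity_violin.png", "class_proportions.png",
                            "track_overlay.png"))
  names(paths) <- c("histogram", "hexbin", "violin", "bars", "overlay")

  if (!nrow(features)) {
    warning("empty feature table: writing placeholder figures")
    for (p in paths) {
      g <- ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "no tracks") +
        ggplot2::theme_void()
      ggplot2::ggsave(p, g, width = 4, height = 3, dpi = 120)
    }
    return(invisible(paths))
  }

  g1 <- ggplot2::ggplot(features, ggplot2::aes(x = .data$duration_s)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey30") +
    ggplot2::labs(x = "track duration (s)", y = "tracks") +
    ggplot2::theme_classic()
  ggplot2::ggsave(paths["histogram"], g1, width = 5, height = 3.5, dpi = 120)

  g2 <- ggplot2::ggplot(features,
                        ggplot2::aes(x = .data$duration_s, y = .data$start_t_s))
  degenerate <- diff(range(features$duration_s)) == 0 ||
    diff(range(features$start_t_s)) == 0
  g2 <- if (degenerate)
    g2 + ggplot2::geom_count(alpha = 0.6)
  else if (requireNamespace("hexbin", quietly = TRUE))
    g2 + ggplot2::geom_hex(bins = 20)
  else g2 + ggplot2::geom_bin2d(bins = 20)
  g2 <- g2 + ggplot2::labs(x = "track duration (s)", y = "start time (s)") +
    ggplot2::theme_classic()
  ggplot2::ggsave(paths["hexbin"], g2, width = 5, height = 3.5, dpi = 120)

  g3 <- ggplot2::ggplot(features,
                        ggplot2::aes(x = .data$duration_class,
                                     y = .data$mean_intensity)) +
    ggplot2::geom_violin(fill = "grey80", scale = "width") +
    ggplot2::geom_jitter(width = 0.1, size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = "duration class", y = "mean track intensity (a.u.)") +
    ggplot2::theme_classic()
  ggplot2::ggsave(paths["violin"], g3, width = 5, height = 3.5, dpi = 120)

  g4 <- ggplot2::ggplot(features,
                        ggplot2::aes(x = .data$duration_class,
                                     fill = .data$profile_class)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(x = "duration class", y = "proportion of tracks",
                  fill = "profile") +
    ggplot2::theme_classic()
  ggplot2::ggsave(paths["bars"], g4, width = 5, height = 3.5, dpi = 120)

  g5 <- .overlayPlot(trackset, movie)
  ggplot2::ggsave(paths["overlay"], g5, width = 5, height = 5, dpi = 120)

  invisible(paths)
}

.overlayPlot <- function(trackset, movie) {
  g <- ggplot2::ggplot()
  if (!is.null(movie)) {
    f1 <- frames(movie)[, , 1]
    px <- pixelSize(movie)
    rast <- data.frame(
      x = as.vector((col(f1) - 0.5) * px),
      y = as.vector((row(f1) - 0.5) * px),
      v = as.vector(f1))
    g <- g + ggplot2::geom_raster(data = rast,
                                  ggplot2::aes(x = .data$x, y = .data$y,
                                               fill = .data$v)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  if (!is.null(trackset) && nrow(trackTable(trackset))) {
    sp <- trackTable(trackset)
    g <- g + ggplot2::geom_path(
      data = sp, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                              group = .data$track_id, colour = .data$t_s),
      linewidth = 0.4) +
      ggplot2::scale_colour_viridis_c(name = "time (s)")
  }
  g + ggplot2::coord_equal() + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (um)", y = "y (um)") + ggplot2::theme_classic()
}
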