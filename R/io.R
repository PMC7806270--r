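#' Write a movie to a multi-page TIFF (with a metadata sidecar)
#'
#' Frames are scaled to [0, 1] by the movie maximum and written as 16-bit
#' pages; pixel size, frame interval, channel and the intensity scale are
#' stored in a YAML sidecar (\code{<path>.yaml}) so the movie round-trips
#' through \code{\link{readMovieTiff}}.
#'
#' @param movie a \code{\linkS4class{MovieStack}}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeMovieTiff <- function(movie, path) {
  stopifnot(is(movie, "MovieStack"))
  d <- movie@data
  scale <- max(d, 1e-12)
  frames <- lapply(seq_len(dim(d)[3]), function(t) d[, , t] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(pixel_size_um = movie@pixelSizeUm,
                        frame_interval_s = movie@frameIntervalS,
                        channel = movie@channelLabel,
                        intensity_scale = scale),
                   paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' Calibration is taken from the YAML sidecar written by
#' \code{\link{writeMovieTiff}} when present; otherwise
#' \code{pixelSizeUm} and \code{frameIntervalS} are required.
#'
#' @param path TIFF path.
#' @param pixelSizeUm,frameIntervalS calibration overrides (required when
#'   no sidecar exists).
#' @param channelLabel channel label override.
#' @return a \code{\linkS4class{MovieStack}}.
#' @export
readMovieTiff <- function(path, pixelSizeUm = NULL, frameIntervalS = NULL,
                          channelLabel = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  meta <- list()
  side <- paste0(path, ".yaml")
  if (file.exists(side)) meta <- yaml::read_yaml(side)
  px <- if (!is.null(pixelSizeUm)) pixelSizeUm else meta$pixel_size_um
  dt <- if (!is.null(frameIntervalS)) frameIntervalS else meta$frame_interval_s
  if (is.null(px) || is.null(dt))
    stop("no metadata sidecar found; supply pixelSizeUm and frameIntervalS")
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  ch <- if (!is.null(channelLabel)) channelLabel
        else if (!is.null(meta$channel)) meta$channel else "ICC"
  d <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (t in seq_along(frames)) d[, , t] <- frames[[t]] * scale
  new("MovieStack", data = d, frameIntervalS = dt, pixelSizeUm = px,
      channelLabel = ch)
}

#' Write a ground-truth schedule as CSV
#'
#' Columns: wave_id, cell_id, site_id, onset_s, duration_s,
#' amplitude_dff, x_um, y_um, channel.
#'
#' @param schedule a \code{GroundTruthSchedule}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeScheduleCsv <- function(schedule, path) {
  cols <- c("wave_id", "cell_id", "site_id", "onset_s", "duration_s",
            "amplitude_dff", "x_um", "y_um", "channel")
  utils::write.csv(as.data.frame(schedule)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write / read a generator configuration as YAML
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param path YAML path.
#' @return \code{path} (write) or a \code{GeneratorConfig} (read).
#' @export
writeConfigYaml <- function(config, path) {
  stopifnot(inherits(config, "GeneratorConfig"))
  vals <- unclass(config)
  vals$condition_scale <- as.list(vals$condition_scale)  # keep names in YAML
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' @rdname writeConfigYaml
#' @export
readConfigYaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$condition_scale))
    vals$condition_scale <- unlist(vals$condition_scale)
  if (!is.null(vals$sites_per_cell_range))
    vals$sites_per_cell_range <- unlist(vals$sites_per_cell_range)
  do.call(generatorConfig, vals)
}

#' Write an occurrence map as CSV
#'
#' One row per site lane (ordered by first activation), one column per
#' frame, 0/1 entries; the first column carries the site id.
#'
#' @param map an \code{\linkS4class{OccurrenceMap}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeOccurrenceCsv <- function(map, path) {
  stopifnot(is(map, "OccurrenceMap"))
  df <- data.frame(site_id = map@siteIds,
                   matrix(as.integer(map@raster), nrow = nrow(map@raster)))
  names(df)[-1] <- paste0("f", seq_len(ncol(map@raster)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a spatiotemporal map as a heat map
#'
#' @param stmap an \code{\linkS4class{STMap}}.
#' @param ... passed to \code{graphics::image}.
#' @export
plotSTMap <- function(stmap, ...) {
  stopifnot(is(stmap, "STMap"))
  tAxis <- (seq_len(ncol(stmap@matrix)) - 0.5) * stmap@frameIntervalS
  graphics::image(x = tAxis, y = stmap@positionsUm, z = t(stmap@matrix),
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "time (s)", ylab = "position (um)",
                  main = sprintf("STMap cell %d", stmap@cellId), ...)
}

#' Plot an occurrence map (site lanes over time)
#'
#' @param map an \code{\linkS4class{OccurrenceMap}}.
#' @param ... passed to \code{graphics::plot}.
#' @export
plotOccurrenceMap <- function(map, ...) {
  stopifnot(is(map, "OccurrenceMap"))
  n <- nrow(map@raster)
  graphics::plot(NA, xlim = c(0, ncol(map@raster) * map@frameIntervalS),
                 ylim = c(0.5, n + 0.5), xlab = "time (s)",
                 ylab = "firing site (lane)", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(n), labels = map@siteIds, las = 1)
  for (i in seq_len(n)) {
    tt <- (which(map@raster[i, ]) - 0.5) * map@frameIntervalS
    if (length(tt))
      graphics::segments(tt, i - 0.4, tt, i + 0.4,
                         col = grDevices::hcl.colors(n, "viridis")[i], lwd = 2)
  }
}
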