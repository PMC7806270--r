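#' Generator configuration for synthetic pacemaker-network movies
#'
#' Builds the parameter set that drives the synthetic movie generator. The
#' defaults are calibrated to the reference measurements of pacemaker
#' calcium signalling in submucosal ICC networks of mouse proximal colon:
#' waves at 14.9 cycles/min propagating at 219 mm/s, whole-cell transients
#' of 2.1 s duration, 1.2 dF/F0 amplitude and 36.8 um spatial spread,
#' 5--12 subcellular firing sites per cell (mean 8.2), soma density
#' 312 cells/mm^2, an ICC-to-SMC activation latency of 56 ms and an
#' SMC-to-displacement latency of 120 ms, imaged at 33 fps.
#'
#' @param ... named overrides of any default listed below.
#'
#' @section Fields:
#' \describe{
#'   \item{fov_width_um, fov_height_um}{field of view, micrometers.}
#'   \item{pixel_size_um}{micrometers per pixel.}
#'   \item{frame_rate_fps}{frames per second, in [1, 200].}
#'   \item{duration_s}{recording length, seconds.}
#'   \item{wave_rate_cpm}{pacemaker wave rate, cycles/min.}
#'   \item{wave_jitter_s}{SD of per-wave onset jitter, seconds.}
#'   \item{event_duration_s, event_duration_sd_s}{whole-cell transient
#'     full-width-at-half-maximum duration, mean and SD, seconds.}
#'   \item{event_amplitude_dff, event_amplitude_sd_dff}{peak dF/F0.}
#'   \item{event_spread_um, event_spread_sd_um}{spatial FWHM, micrometers.}
#'   \item{wave_velocity_mm_s}{propagation velocity, mm/s.}
#'   \item{sites_per_cell_mean, sites_per_cell_sd, sites_per_cell_range}{
#'     firing-site count distribution (discretised truncated normal).}
#'   \item{within_wave_decay_tau_s}{exponential decay constant of
#'     site-firing intensity inside a wave, seconds.}
#'   \item{extra_firings_mean}{mean number of extra firings per site per
#'     wave beyond the guaranteed first (Poisson).}
#'   \item{background_firing_hz}{rate of stochastic, wave-independent
#'     site firings (per site, single-cell mode); emulates the residual
#'     stochastic firing seen when clustered pacemaker activity is
#'     pharmacologically suppressed. Default 0.}
#'   \item{indicator_rise_s, indicator_decay_s}{indicator kinetics
#'     (GCaMP6f-like), seconds.}
#'   \item{noise_sd_dff}{additive Gaussian noise SD in dF/F0 units.}
#'   \item{cell_density_per_mm2}{soma density, cells/mm^2.}
#'   \item{min_separation_um}{hard-core minimum soma separation, um.}
#'   \item{nn_separation_um}{target mean nearest-neighbour separation used
#'     by the rescale-to-target mode of \code{\link{generateCellField}}.}
#'   \item{cell_length_um, cell_width_um, soma_radius_um}{cell footprint.}
#'   \item{site_spacing_um, site_spread_um, site_event_duration_s}{
#'     subcellular firing-site layout and site-level transient geometry.}
#'   \item{baseline_f0}{baseline fluorescence, arbitrary units.}
#'   \item{icc_smc_latency_ms, smc_disp_latency_ms}{dual-channel lags.}
#'   \item{condition_scale}{named multipliers (rate, amplitude, duration)
#'     recording applied pharmacological-condition scaling.}
#'   \item{seed}{integer RNG seed.}
#' }
#'
#' @return a list of class \code{"GeneratorConfig"}.
#' @examples
#' cfg <- generatorConfig(duration_s = 10, fov_width_um = 64)
#' cfg$wave_rate_cpm
#' @export
generatorConfig <- function(...) {
  cfg <- list(
    fov_width_um        = 128,
    fov_height_um       = 128,
    pixel_size_um       = 1.0,
    frame_rate_fps      = 33,
    duration_s          = 60,
    wave_rate_cpm       = 14.9,
    wave_jitter_s       = 0.15,
    event_duration_s    = 2.1,
    event_duration_sd_s = 0.2,
    event_amplitude_dff = 1.2,
    event_amplitude_sd_dff = 0.05,
    event_spread_um     = 36.8,
    event_spread_sd_um  = 1.5,
    wave_velocity_mm_s  = 219,
    sites_per_cell_mean = 8.2,
    sites_per_cell_sd   = 2,
    sites_per_cell_range = c(5L, 12L),
    within_wave_decay_tau_s = 0.15,
    extra_firings_mean  = 0.6,
    background_firing_hz = 0,
    indicator_rise_s    = 0.06,
    indicator_decay_s   = 0.2,
    noise_sd_dff        = 0.05,
    cell_density_per_mm2 = 312,
    min_separation_um   = 40,
    nn_separation_um    = 49.3,
    cell_length_um      = 100,
    cell_width_um       = 12,
    soma_radius_um      = 5,
    site_spacing_um     = 10,
    site_spread_um      = 3.5,
    site_event_duration_s = 0.5,
    baseline_f0         = 100,
    background_offset   = 10,
    icc_smc_latency_ms  = 56,
    smc_disp_latency_ms = 120,
    condition_scale     = c(rate = 1, amplitude = 1, duration = 1),
    seed                = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown GeneratorConfig field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validateConfig(cfg)
  structure(cfg, class = "GeneratorConfig")
}

validateConfig <- function(cfg) {
  pos <- c("fov_width_um", "fov_height_um", "pixel_size_um", "duration_s",
           "event_duration_s", "event_amplitude_dff", "event_spread_um",
           "wave_velocity_mm_s", "indicator_rise_s", "indicator_decay_s",
           "cell_length_um", "cell_width_um", "site_spacing_um",
           "site_spread_um", "site_event_duration_s", "baseline_f0")
  for (f in pos)
    stopIfNot(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] > 0,
              paste0("GeneratorConfig field '", f, "' must be a single positive number"))
  nonneg <- c("wave_rate_cpm", "wave_jitter_s", "noise_sd_dff",
              "cell_density_per_mm2", "within_wave_decay_tau_s",
              "icc_smc_latency_ms", "smc_disp_latency_ms",
              "extra_firings_mean", "min_separation_um",
              "background_firing_hz")
  for (f in nonneg)
    stopIfNot(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 0,
              paste0("GeneratorConfig field '", f, "' must be >= 0"))
  stopIfNot(cfg$frame_rate_fps >= 1 && cfg$frame_rate_fps <= 200,
            "frame_rate_fps must lie in [1, 200]")
  rng <- cfg$sites_per_cell_range
  stopIfNot(length(rng) == 2 && all(rng >= 1) && rng[1] <= rng[2],
            "sites_per_cell_range must be c(lo, hi) with 1 <= lo <= hi")
  stopIfNot(all(cfg$condition_scale >= 0), "condition_scale must be >= 0")
  invisible(cfg)
}

#' @export
print.GeneratorConfig <- function(x, ...) {
  cat(sprintf(
    "GeneratorConfig: %g x %g um FOV @ %g um/px, %g s @ %g fps\n",
    x$fov_width_um, x$fov_height_um, x$pixel_size_um,
    x$duration_s, x$frame_rate_fps))
  cat(sprintf(
    "  waves %.1f cpm @ %g mm/s; events %.1f s, %.1f dF/F0, %.1f um FWHM\n",
    x$wave_rate_cpm, x$wave_velocity_mm_s, x$event_duration_s,
    x$event_amplitude_dff, x$event_spread_um))
  cat(sprintf("  condition scale: rate %g, amplitude %g, duration %g; seed %d\n",
              x$condition_scale[["rate"]], x$condition_scale[["amplitude"]],
              x$condition_scale[["duration"]], as.integer(x$seed)))
  invisible(x)
}

#' Apply a pharmacological-condition scaling to a generator configuration
#'
#' Drug conditions are emulated phenomenologically as multipliers on event
#' rate, amplitude and duration (e.g. an L-type channel blocker that
#' abolishes transients is \code{rate = 0}). \code{scale = 1} is the
#' identity.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param rate,amplitude,duration non-negative multipliers.
#' @return a modified copy of \code{config}.
#' @examples
#' ctl <- generatorConfig()
#' nic <- applyCondition(ctl, rate = 0.105)  # nicardipine-like readout scale
#' @export
applyCondition <- function(config, rate = 1, amplitude = 1, duration = 1) {
  stopifnot(inherits(config, "GeneratorConfig"))
  stopIfNot(rate >= 0 && amplitude >= 0 && duration >= 0,
            "condition multipliers must be >= 0")
  config$wave_rate_cpm        <- config$wave_rate_cpm * rate
  config$event_amplitude_dff  <- config$event_amplitude_dff * amplitude
  config$event_duration_s     <- config$event_duration_s * duration
  config$site_event_duration_s <- config$site_event_duration_s * duration
  config$condition_scale <- config$condition_scale *
    c(rate = rate, amplitude = amplitude, duration = duration)
  validateConfig(config)
  config
}

#' Generate a synthetic ICC network layout
#'
#' Places elongated cells in the field of view as a hard-core point process
#' (Poisson-distributed count at the configured soma density, minimum
#' inter-soma separation \code{min_separation_um}) and assigns each cell a
#' number of subcellular firing sites drawn from the configured discretised
#' normal distribution truncated to \code{sites_per_cell_range}, laid out
#' along the cell axis at \code{site_spacing_um} spacing.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param seed RNG seed; defaults to \code{config$seed}.
#' @return an object of class \code{"CellGeometry"}: a list with elements
#'   \code{cells} (data.frame: cell_id, x_um, y_um, theta, axis_t_min,
#'   axis_t_max, n_sites) and \code{sites} (data.frame: cell_id, site_id,
#'   x_um, y_um).
#' @export
generateNetworkGeometry <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "GeneratorConfig"))
  fw <- config$fov_width_um; fh <- config$fov_height_um
  if (config$cell_density_per_mm2 > 0 &&
      (fw < 2 * config$soma_radius_um || fh < 2 * config$soma_radius_um))
    stop("FOV too small to place one cell (", fw, " x ", fh, " um)")
  withSeed(seed, {
    areaMm2 <- fw * fh / 1e6
    n <- stats::rpois(1, config$cell_density_per_mm2 * areaMm2)
    cells <- placeHardCore(n, fw, fh, config$min_separation_um)
    n <- nrow(cells)
    if (n == 0) {
      return(structure(list(
        cells = data.frame(cell_id = integer(0), x_um = numeric(0),
                           y_um = numeric(0), theta = numeric(0),
                           axis_t_min = numeric(0), axis_t_max = numeric(0),
                           n_sites = integer(0)),
        sites = data.frame(cell_id = integer(0), site_id = integer(0),
                           x_um = numeric(0), y_um = numeric(0)),
        fov_um = c(width = fw, height = fh)), class = "CellGeometry"))
    }
    theta <- stats::runif(n, 0, 2 * pi)
    h <- config$cell_length_um / 2
    margin <- 1
    tmin <- numeric(n); tmax <- numeric(n)
    for (i in seq_len(n)) {
      rg <- clipSegment(cells$x[i], cells$y[i], theta[i], h, fw, fh, margin)
      tmin[i] <- rg[1]; tmax[i] <- rg[2]
    }
    nSites <- drawSiteCounts(n, config)
    cellsDf <- data.frame(cell_id = seq_len(n), x_um = cells$x, y_um = cells$y,
                          theta = theta, axis_t_min = tmin, axis_t_max = tmax,
                          n_sites = nSites)
    sites <- placeSites(cellsDf, config)
    cellsDf$n_sites <- as.integer(tabulate(sites$cell_id, nbins = n))
    structure(list(cells = cellsDf, sites = sites,
                   fov_um = c(width = fw, height = fh)),
              class = "CellGeometry")
  })
}

# sequential-inhibition placement; keeps as many of n as fit
placeHardCore <- function(n, fw, fh, minSep) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L; maxAttempts <- 20000L + 2000L * n
  while (length(xs) < n && attempts < maxAttempts) {
    attempts <- attempts + 1L
    px <- stats::runif(1, 0, fw); py <- stats::runif(1, 0, fh)
    if (length(xs) == 0 ||
        min((xs - px)^2 + (ys - py)^2) >= minSep^2) {
      xs <- c(xs, px); ys <- c(ys, py)
    }
  }
  data.frame(x = xs, y = ys)
}

# intersect the parametric axis segment with the FOV rectangle
clipSegment <- function(cx, cy, theta, h, fw, fh, margin) {
  dx <- cos(theta); dy <- sin(theta)
  lo <- -h; hi <- h
  for (b in list(c(dx, cx, margin, fw - margin), c(dy, cy, margin, fh - margin))) {
    d <- b[1]; c0 <- b[2]
    if (abs(d) > 1e-12) {
      t1 <- (b[3] - c0) / d; t2 <- (b[4] - c0) / d
      lo <- max(lo, min(t1, t2)); hi <- min(hi, max(t1, t2))
    }
  }
  if (lo > hi) { lo <- 0; hi <- 0 }
  c(lo, hi)
}

drawSiteCounts <- function(n, config) {
  rng <- config$sites_per_cell_range
  out <- integer(n)
  for (i in seq_len(n)) {
    k <- -1L
    while (k < rng[1] || k > rng[2])
      k <- as.integer(round(stats::rnorm(1, config$sites_per_cell_mean,
                                         config$sites_per_cell_sd)))
    out[i] <- k
  }
  out
}

placeSites <- function(cellsDf, config) {
  res <- list(); sid <- 0L
  for (i in seq_len(nrow(cellsDf))) {
    cl <- cellsDf[i, ]
    span <- cl$axis_t_max - cl$axis_t_min
    slots <- floor(span / config$site_spacing_um)
    if (slots < 1) next
    grid <- cl$axis_t_min + config$site_spacing_um * (seq_len(slots) - 0.5)
    k <- min(cl$n_sites, slots)
    tSel <- sort(sample(grid, k)) + stats::runif(k, -2, 2)
    perp <- stats::runif(k, -config$cell_width_um / 4, config$cell_width_um / 4)
    x <- cl$x_um + tSel * cos(cl$theta) - perp * sin(cl$theta)
    y <- cl$y_um + tSel * sin(cl$theta) + perp * cos(cl$theta)
    res[[length(res) + 1L]] <- data.frame(
      cell_id = cl$cell_id, site_id = sid + seq_len(k), x_um = x, y_um = y)
    sid <- sid + k
  }
  if (length(res) == 0)
    return(data.frame(cell_id = integer(0), site_id = integer(0),
                      x_um = numeric(0), y_um = numeric(0)))
  do.call(rbind, res)
}

#' Indicator-support mask for a cell geometry
#'
#' Logical H x W matrix marking pixels on any cell footprint: within
#' \code{cell_width_um / 2} of a cell axis or within \code{soma_radius_um}
#' of a soma centre.
#'
#' @param geometry a \code{CellGeometry}.
#' @param config a \code{\link{generatorConfig}} giving pixel size, FOV and
#'   footprint dimensions.
#' @return logical matrix, \code{TRUE} on cell footprints.
#' @export
footprintMask <- function(geometry, config) {
  masks <- cellFootprints(geometry, config)
  px <- config$pixel_size_um
  H <- round(config$fov_height_um / px)
  W <- round(config$fov_width_um / px)
  M <- matrix(FALSE, H, W)
  for (m in masks) M <- M | m
  M
}

# per-cell footprint masks (list indexed like geometry$cells rows)
cellFootprints <- function(geometry, config) {
  px <- config$pixel_size_um
  H <- round(config$fov_height_um / px)
  W <- round(config$fov_width_um / px)
  if (nrow(geometry$cells) == 0) return(list())
  xc <- (seq_len(W) - 0.5) * px
  yc <- (seq_len(H) - 0.5) * px
  X <- matrix(xc, H, W, byrow = TRUE)
  Y <- matrix(yc, H, W)
  hwid <- config$cell_width_um / 2
  lapply(seq_len(nrow(geometry$cells)), function(i) {
    cl <- geometry$cells[i, ]
    dxv <- cos(cl$theta); dyv <- sin(cl$theta)
    tproj <- (X - cl$x_um) * dxv + (Y - cl$y_um) * dyv
    tcl <- pmin(pmax(tproj, cl$axis_t_min), cl$axis_t_max)
    d2 <- (X - (cl$x_um + tcl * dxv))^2 + (Y - (cl$y_um + tcl * dyv))^2
    (d2 <= hwid^2) |
      ((X - cl$x_um)^2 + (Y - cl$y_um)^2 <= config$soma_radius_um^2)
  })
}

#' Select cells suitable for per-cell spatiotemporal readouts
#'
#' Per-cell transient metrics (duration, amplitude, spatial spread) are
#' only meaningful for cells that are fully in view over the event's
#' half-maximum extent and whose footprint does not intersect another
#' cell's (shared pixels carry both cells' fluorescence). Returns the ids
#' of cells whose axis covers at least \code{minAxisHalfUm} on both sides
#' of the soma and whose footprint is disjoint from all others.
#'
#' @param geometry a \code{CellGeometry}.
#' @param config the \code{\link{generatorConfig}} used to build it.
#' @param minAxisHalfUm required in-view axis half-length, micrometers.
#' @return integer vector of cell ids (possibly empty).
#' @export
selectAnalysisCells <- function(geometry, config, minAxisHalfUm = 25) {
  cl <- geometry$cells
  if (nrow(cl) == 0) return(integer(0))
  ok <- cl$axis_t_min <= -minAxisHalfUm & cl$axis_t_max >= minAxisHalfUm
  if (nrow(cl) > 1) {
    masks <- cellFootprints(geometry, config)
    for (i in seq_len(nrow(cl))) {
      if (!ok[i]) next
      for (j in seq_len(nrow(cl))) {
        if (i == j) next
        if (any(masks[[i]] & masks[[j]])) { ok[i] <- FALSE; break }
      }
    }
  }
  cl$cell_id[ok]
}

#' @export
print.CellGeometry <- function(x, ...) {
  cat(sprintf("CellGeometry: %d cells, %d firing sites in %g x %g um FOV\n",
              nrow(x$cells), nrow(x$sites),
              x$fov_um[["width"]], x$fov_um[["height"]]))
  invisible(x)
}

#' Axis polyline of one cell
#'
#' @param geometry a \code{CellGeometry}.
#' @param cellId integer cell id.
#' @return two-column matrix of (x_um, y_um) endpoints of the cell axis.
#' @export
cellAxis <- function(geometry, cellId) {
  cl <- geometry$cells[geometry$cells$cell_id == cellId, ]
  stopIfNot(nrow(cl) == 1, paste("no such cell:", cellId))
  t(vapply(c(cl$axis_t_min, cl$axis_t_max), function(t)
    c(cl$x_um + t * cos(cl$theta), cl$y_um + t * sin(cl$theta)),
    numeric(2)))
}

#' Schedule calcium-transient clusters for a synthetic recording
#'
#' Wave onsets occur at mean interval \code{60/wave_rate_cpm} s with
#' Gaussian per-onset jitter and a uniformly random phase, so the expected
#' wave count equals \code{wave_rate_cpm * duration_s / 60}. Each wave
#' originates at a uniformly chosen cell and reaches every other cell with
#' a delay of distance/velocity. In \code{"network"} mode one whole-cell
#' transient is scheduled per cell per wave (low-magnification regime); in
#' \code{"single_cell"} mode each subcellular site fires one or more
#' site-level transients at times drawn from an exponentially decaying
#' intensity (\code{within_wave_decay_tau_s}) after the cell's wave onset,
#' so most firings fall within the first ~256 ms of the wave.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param geometry a \code{CellGeometry} (non-empty).
#' @param mode \code{"network"} or \code{"single_cell"}.
#' @param seed RNG seed; defaults to \code{config$seed}.
#' @return a \code{GroundTruthSchedule} data.frame with columns wave_id,
#'   cell_id, site_id, onset_s, duration_s, amplitude_dff, spread_um,
#'   x_um, y_um, channel, sorted by onset.
#' @export
scheduleCtcs <- function(config, geometry, mode = c("network", "single_cell"),
                         seed = config$seed) {
  stopifnot(inherits(config, "GeneratorConfig"),
            inherits(geometry, "CellGeometry"))
  mode <- match.arg(mode)
  stopIfNot(nrow(geometry$cells) > 0, "geometry is empty (no cells)")
  emptySchedule <- function() {
    structure(data.frame(wave_id = integer(0), cell_id = integer(0),
                         site_id = integer(0), onset_s = numeric(0),
                         duration_s = numeric(0), amplitude_dff = numeric(0),
                         spread_um = numeric(0), x_um = numeric(0),
                         y_um = numeric(0), channel = character(0)),
              class = c("GroundTruthSchedule", "data.frame"), mode = mode)
  }
  if (config$wave_rate_cpm <= 0 && config$background_firing_hz <= 0)
    return(emptySchedule())
  withSeed(seed, {
    if (config$wave_rate_cpm > 0) {
      interval <- 60 / config$wave_rate_cpm
      phase <- stats::runif(1, 0, interval)
      base <- seq(phase - interval, config$duration_s + interval,
                  by = interval)
      onsets <- base + stats::rnorm(length(base), 0, config$wave_jitter_s)
      onsets <- sort(onsets[onsets >= 0 & onsets < config$duration_s])
    } else onsets <- numeric(0)
    if (length(onsets) == 0 && config$background_firing_hz <= 0)
      return(emptySchedule())
    cells <- geometry$cells
    vUmS <- config$wave_velocity_mm_s * 1000
    rows <- vector("list", length(onsets))
    for (w in seq_along(onsets)) {
      org <- sample(nrow(cells), 1)
      d <- sqrt((cells$x_um - cells$x_um[org])^2 +
                (cells$y_um - cells$y_um[org])^2)
      cellOnset <- onsets[w] + d / vUmS
      if (mode == "network") {
        nc <- nrow(cells)
        # the transient plateau is a property of the shared pacemaker
        # event: one duration per wave, small per-cell scatter on top
        durW <- pmax(0.3, stats::rnorm(1, config$event_duration_s,
                                       config$event_duration_sd_s))
        rows[[w]] <- data.frame(
          wave_id = w, cell_id = cells$cell_id, site_id = 0L,
          onset_s = cellOnset,
          duration_s = pmax(0.3, durW + stats::rnorm(nc, 0, 0.05)),
          amplitude_dff = pmax(0.2, stats::rnorm(nc, config$event_amplitude_dff,
                                                 config$event_amplitude_sd_dff)),
          spread_um = pmax(5, stats::rnorm(nc, config$event_spread_um,
                                           config$event_spread_sd_um)),
          x_um = cells$x_um, y_um = cells$y_um, channel = "ICC")
      } else {
        st <- geometry$sites
        co <- cellOnset[match(st$cell_id, cells$cell_id)]
        per <- lapply(seq_len(nrow(st)), function(i) {
          nFir <- 1L + stats::rpois(1, config$extra_firings_mean)
          tau <- config$within_wave_decay_tau_s
          delays <- if (tau > 0) stats::rexp(nFir, rate = 1 / tau)
                    else rep(0, nFir)
          data.frame(
            wave_id = w, cell_id = st$cell_id[i], site_id = st$site_id[i],
            onset_s = co[i] + sort(delays),
            duration_s = pmax(0.15, stats::rnorm(nFir, config$site_event_duration_s,
                                                 0.1 * config$site_event_duration_s)),
            amplitude_dff = pmax(0.2, stats::rnorm(nFir, config$event_amplitude_dff,
                                                   config$event_amplitude_sd_dff)),
            spread_um = pmax(1, stats::rnorm(nFir, config$site_spread_um, 0.3)),
            x_um = st$x_um[i], y_um = st$y_um[i], channel = "ICC")
        })
        rows[[w]] <- do.call(rbind, per)
      }
    }
    if (mode == "single_cell" && config$background_firing_hz > 0) {
      # stochastic, wave-independent site firings (suppressed-pacemaker
      # regime); wave_id 0 marks them as background in the ground truth
      st <- geometry$sites
      bg <- lapply(seq_len(nrow(st)), function(i) {
        nB <- stats::rpois(1, config$background_firing_hz * config$duration_s)
        if (nB == 0) return(NULL)
        data.frame(
          wave_id = 0L, cell_id = st$cell_id[i], site_id = st$site_id[i],
          onset_s = sort(stats::runif(nB, 0, config$duration_s)),
          duration_s = pmax(0.15, stats::rnorm(nB, config$site_event_duration_s,
                                               0.1 * config$site_event_duration_s)),
          amplitude_dff = pmax(0.2, stats::rnorm(nB, config$event_amplitude_dff,
                                                 config$event_amplitude_sd_dff)),
          spread_um = pmax(1, stats::rnorm(nB, config$site_spread_um, 0.3)),
          x_um = st$x_um[i], y_um = st$y_um[i], channel = "ICC")
      })
      rows <- c(rows, bg)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(emptySchedule())
    sch <- do.call(rbind, rows)
    sch <- sch[sch$onset_s >= 0 & sch$onset_s < config$duration_s, ]
    sch <- sch[order(sch$onset_s), ]
    rownames(sch) <- NULL
    structure(sch, class = c("GroundTruthSchedule", "data.frame"), mode = mode)
  })
}

#' Render a synthetic fluorescence movie from a ground-truth schedule
#'
#' Forward imaging model: raw intensity
#' \deqn{F(x,t) = b + F_0 M(x) (1 + A(x,t)) + \epsilon}
#' where \code{b = background_offset} is a spatially uniform non-indicator
#' background, \code{M(x)} is the indicator support (1 on cell footprints,
#' 0 elsewhere, so indicator-free pixels stay dark), and each scheduled
#' firing adds to \code{A} a separable spatial Gaussian (FWHM =
#' \code{spread_um}) times a rise-plateau-decay time course whose width at
#' half-maximum equals \code{duration_s}, scaled so the peak dF/F0 equals
#' \code{amplitude_dff}. Additive Gaussian noise of SD \code{noise_sd_dff}
#' (in dF/F0 units, i.e. \code{noise_sd_dff * baseline_f0} raw units) is
#' applied everywhere; pixel values are clipped at 0. Baseline is positive
#' everywhere (\code{b > 0}); after scalar background subtraction the
#' pixelwise dF/F0 of a footprint pixel equals \code{A} exactly.
#'
#' @param geometry a \code{CellGeometry} (used for FOV bounds checking).
#' @param schedule a \code{GroundTruthSchedule}.
#' @param config a \code{\link{generatorConfig}}.
#' @param channelLabel label stored in the returned stack.
#' @param noiseSd noise SD override (dF/F0 units).
#' @param seed RNG seed for the noise; defaults to \code{config$seed + 1}.
#' @return a \code{\linkS4class{MovieStack}}.
#' @export
renderMovie <- function(geometry, schedule, config, channelLabel = "ICC",
                        noiseSd = config$noise_sd_dff,
                        seed = config$seed + 1L) {
  stopifnot(inherits(config, "GeneratorConfig"))
  px <- config$pixel_size_um
  H <- round(config$fov_height_um / px)
  W <- round(config$fov_width_um / px)
  T <- round(config$duration_s * config$frame_rate_fps)
  dt <- 1 / config$frame_rate_fps
  if (nrow(schedule) > 0) {
    bad <- which(schedule$x_um < 0 | schedule$x_um > config$fov_width_um |
                 schedule$y_um < 0 | schedule$y_um > config$fov_height_um |
                 schedule$onset_s < 0 | schedule$onset_s >= config$duration_s)
    if (length(bad))
      stop("schedule row ", bad[1], " lies outside the FOV or time range")
  }
  A <- array(0, dim = c(H, W, T))
  tFrames <- (seq_len(T) - 1) * dt
  xc <- (seq_len(W) - 0.5) * px
  yc <- (seq_len(H) - 0.5) * px
  masks <- cellFootprints(geometry, config)
  M <- matrix(FALSE, H, W)
  for (mm in masks) M <- M | mm
  cellRow <- match(schedule$cell_id, geometry$cells$cell_id)
  for (i in seq_len(nrow(schedule))) {
    r <- schedule[i, ]
    sig <- r$spread_um / (2 * sqrt(2 * log(2)))
    rad <- 3.5 * sig
    cLo <- max(1L, floor((r$x_um - rad) / px)); cHi <- min(W, ceiling((r$x_um + rad) / px))
    rLo <- max(1L, floor((r$y_um - rad) / px)); rHi <- min(H, ceiling((r$y_um + rad) / px))
    if (cLo > cHi || rLo > rHi) next
    p <- plateauEnd(r$duration_s, config$indicator_rise_s, config$indicator_decay_s)
    tEnd <- r$onset_s + p + config$indicator_decay_s * log(1e3 * r$amplitude_dff)
    fLo <- max(1L, 1L + floor(r$onset_s / dt))
    fHi <- min(T, 1L + ceiling(tEnd / dt))
    if (fLo > fHi) next
    gx <- exp(-(xc[cLo:cHi] - r$x_um)^2 / (2 * sig^2))
    gy <- exp(-(yc[rLo:rHi] - r$y_um)^2 / (2 * sig^2))
    k <- r$amplitude_dff * transientKernel(tFrames[fLo:fHi] - r$onset_s,
                                           r$duration_s,
                                           config$indicator_rise_s,
                                           config$indicator_decay_s)
    patch <- outer(gy, gx)
    # a transient is fluorescence of the firing cell's own cytoplasm:
    # restrict its support to that cell's footprint
    if (!is.na(cellRow[i]))
      patch <- patch * masks[[cellRow[i]]][rLo:rHi, cLo:cHi]
    incr <- array(outer(as.vector(patch), k),
                  dim = c(length(gy), length(gx), length(k)))
    A[rLo:rHi, cLo:cHi, fLo:fHi] <-
      A[rLo:rHi, cLo:cHi, fLo:fHi, drop = FALSE] + incr
  }
  F <- config$background_offset + config$baseline_f0 * as.vector(M) * (1 + A)
  rm(A)
  if (noiseSd > 0) {
    withSeed(seed, {
      F <- F + stats::rnorm(length(F), sd = config$baseline_f0 * noiseSd)
    })
  }
  F[F < 0] <- 0
  new("MovieStack", data = F, frameIntervalS = dt, pixelSizeUm = px,
      channelLabel = channelLabel)
}

#' Generate a complete synthetic network recording
#'
#' Convenience wrapper: geometry + network-mode schedule + rendered movie.
#' This is the low-magnification regime in which each cell shows one
#' whole-cell transient per pacemaker wave.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param seed RNG seed; defaults to \code{config$seed}.
#' @return list with elements \code{movie} (\code{MovieStack}),
#'   \code{schedule} (\code{GroundTruthSchedule}) and \code{geometry}.
#' @examples
#' rec <- generateNetworkMovie(generatorConfig(duration_s = 8,
#'   fov_width_um = 64, fov_height_um = 64), seed = 7)
#' rec$movie
#' @export
generateNetworkMovie <- function(config = generatorConfig(),
                                 seed = config$seed) {
  geom <- generateNetworkGeometry(config, seed = seed)
  if (nrow(geom$cells) == 0)
    stop("generated geometry has no cells; enlarge the FOV or raise density")
  sch <- scheduleCtcs(config, geom, mode = "network", seed = seed + 101L)
  mov <- renderMovie(geom, sch, config, seed = seed + 202L)
  list(movie = mov, schedule = sch, geometry = geom)
}

#' Generate a synthetic single-cell recording with planted firing sites
#'
#' High-magnification regime: one horizontal cell centred in a small FOV,
#' its site count drawn from the configured distribution, each site firing
#' site-level transients (small spatial spread) inside every wave. The
#' returned schedule is the ground truth for initiation-site recovery.
#'
#' @param config a \code{\link{generatorConfig}}; FOV/duration defaults are
#'   overridden to a single-cell geometry unless already customised.
#' @param seed RNG seed.
#' @return list with \code{movie}, \code{schedule}, \code{geometry}, and
#'   \code{nSitesPlanted}.
#' @export
generateSingleCellMovie <- function(config = generatorConfig(
                                      fov_width_um = 150, fov_height_um = 40,
                                      duration_s = 30, cell_length_um = 130),
                                    seed = config$seed) {
  stopifnot(inherits(config, "GeneratorConfig"))
  geom <- withSeed(seed, {
    cx <- config$fov_width_um / 2; cy <- config$fov_height_um / 2
    h <- config$cell_length_um / 2
    rg <- clipSegment(cx, cy, 0, h, config$fov_width_um,
                      config$fov_height_um, 1)
    cellsDf <- data.frame(cell_id = 1L, x_um = cx, y_um = cy, theta = 0,
                          axis_t_min = rg[1], axis_t_max = rg[2],
                          n_sites = drawSiteCounts(1, config))
    sites <- placeSites(cellsDf, config)
    cellsDf$n_sites <- nrow(sites)
    structure(list(cells = cellsDf, sites = sites,
                   fov_um = c(width = config$fov_width_um,
                              height = config$fov_height_um)),
              class = "CellGeometry")
  })
  sch <- scheduleCtcs(config, geom, mode = "single_cell", seed = seed + 101L)
  mov <- renderMovie(geom, sch, config, seed = seed + 202L)
  list(movie = mov, schedule = sch, geometry = geom,
       nSitesPlanted = geom$cells$n_sites[1])
}

#' Generate a pixel-matched dual-channel recording (ICC + SMC) with a
#' displacement trace
#'
#' The SMC channel copies every ICC transient delayed by
#' \code{icc_smc_latency_ms}; the displacement trace is a smoothed pulse
#' train lagging the SMC events by a further \code{smc_disp_latency_ms},
#' built from the same transient kernel so that onset estimation is
#' comparable across the three signals. Both movies share one geometry
#' (pixel-matched ROIs apply to either channel).
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param seed RNG seed.
#' @return list with \code{icc}, \code{smc} (\code{MovieStack}s),
#'   \code{displacement} (numeric trace, one value per frame),
#'   \code{schedule} (both channels stacked) and \code{geometry}.
#' @export
generateDualChannel <- function(config = generatorConfig(), seed = config$seed) {
  stopifnot(inherits(config, "GeneratorConfig"))
  stopIfNot(config$icc_smc_latency_ms >= 0 && config$smc_disp_latency_ms >= 0,
            "latencies must be >= 0")
  geom <- generateNetworkGeometry(config, seed = seed)
  if (nrow(geom$cells) == 0)
    stop("generated geometry has no cells; enlarge the FOV or raise density")
  schIcc <- scheduleCtcs(config, geom, mode = "network", seed = seed + 101L)
  schSmc <- schIcc
  schSmc$onset_s <- schSmc$onset_s + config$icc_smc_latency_ms / 1000
  schSmc$channel <- "SMC"
  schSmc <- schSmc[schSmc$onset_s < config$duration_s, ]
  movIcc <- renderMovie(geom, schIcc, config, channelLabel = "ICC",
                        seed = seed + 202L)
  movSmc <- renderMovie(geom, schSmc, config, channelLabel = "SMC",
                        seed = seed + 303L)
  T <- nFrames(movIcc)
  tFrames <- (seq_len(T) - 1) * frameInterval(movIcc)
  disp <- numeric(T)
  for (i in seq_len(nrow(schSmc))) {
    r <- schSmc[i, ]
    disp <- disp + r$amplitude_dff *
      transientKernel(tFrames - (r$onset_s + config$smc_disp_latency_ms / 1000),
                      r$duration_s, config$indicator_rise_s,
                      config$indicator_decay_s)
  }
  if (nrow(schSmc) > 0) disp <- disp / nrow(schSmc) * max(1, nrow(geom$cells))
  withSeed(seed + 404L, {
    disp <- disp + stats::rnorm(T, sd = 0.005 * max(disp, 1))
  })
  sch <- rbind(schIcc, schSmc)
  sch <- sch[order(sch$onset_s), ]
  rownames(sch) <- NULL
  class(sch) <- c("GroundTruthSchedule", "data.frame")
  list(icc = movIcc, smc = movSmc, displacement = disp,
       schedule = sch, geometry = geom)
}
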