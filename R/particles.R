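#' Threshold a dF/F0 stack into active/inactive pixels
#'
#' A pixel-frame is active when its dF/F0 exceeds the pixel's baseline
#' mean plus \code{kSd} baseline-noise SDs. Both statistics come from the
#' sub-baseline residual (dF/F0 values below 0), which is immune to
#' contamination by the transients themselves: because F0 is the
#' \code{p}-th temporal percentile, under Gaussian baseline noise the
#' residual is the lower-tail of a normal whose mean sits
#' \code{-qnorm(p)} SDs above F0, so the tail RMS is rescaled by the
#' truncated-normal factor \code{sqrt(1 + a^2 - a*dnorm(a)/p)} (with
#' \code{a = -qnorm(p)}) to recover the SD, and the baseline mean is
#' \code{a} SDs. Masked-out pixels are never active.
#'
#' @param dff a \code{\linkS4class{DffStack}}.
#' @param kSd threshold in baseline-noise SDs above the baseline mean.
#'   The default 4.5 was calibrated on noise-only synthetic movies so
#'   that the expected number of noise-born particles per 60-s movie is
#'   of order one; a 3-SD cut admits ~0.1\% of all pixel-frames, which
#'   at movie scale is thousands of false pixels.
#' @return logical array (H x W x T) of active pixel-frames.
#' @export
thresholdDff <- function(dff, kSd = 4.5) {
  stopifnot(is(dff, "DffStack"))
  d <- dff@data
  H <- dim(d)[1]; W <- dim(d)[2]; T <- dim(d)[3]
  m <- d
  dim(m) <- c(H * W, T)
  p <- dff@f0Percentile
  a <- -stats::qnorm(p)                       # baseline mean above F0, in SDs
  cf <- sqrt(max(1e-6, 1 + a^2 - a * stats::dnorm(a) / p))
  neg <- pmin(m, 0)
  nNeg <- rowSums(m < 0)
  sig <- sqrt(rowSums(neg * neg) / pmax(1, nNeg)) / cf
  sig[nNeg == 0] <- NA
  med <- stats::median(sig, na.rm = TRUE)
  if (!is.finite(med)) med <- 0
  sig[is.na(sig)] <- med
  act <- m > ((a + kSd) * sig)
  act[!as.vector(dff@mask), ] <- FALSE
  dim(act) <- c(H, W, T)
  act
}

#' Label the particles (PTCLs) of one binary frame
#'
#' Flood-fill connected-component labelling of the active pixels of a
#' frame, implemented as run-based union-find (equivalent to breadth-first
#' flood fill). Components smaller than \code{minAreaPx} pixels are
#' discarded as shot noise.
#'
#' @param binaryFrame logical matrix of active pixels.
#' @param connectivity 8 (default, diagonals connect) or 4.
#' @param minAreaPx minimum particle area in pixels.
#' @param pixelSizeUm micrometers per pixel, for areas and centroids.
#' @return list with \code{labels} (integer matrix, 0 = background),
#'   \code{particles} (data.frame: label, area_px, area_um2, centroid_x_um,
#'   centroid_y_um) and \code{pixels} (list of linear pixel-index vectors,
#'   one per particle).
#' @export
labelParticles <- function(binaryFrame, connectivity = 8, minAreaPx = 4,
                           pixelSizeUm = 1) {
  stopifnot(is.matrix(binaryFrame))
  lab <- labelBinary(binaryFrame, connectivity)
  K <- max(lab)
  if (K == 0) {
    return(list(labels = lab,
                particles = emptyParticles(),
                pixels = list()))
  }
  idx <- which(lab > 0L)
  lv <- lab[idx]
  sizes <- tabulate(lv, nbins = K)
  keep <- which(sizes >= minAreaPx)
  if (length(keep) == 0) {
    lab[] <- 0L
    return(list(labels = lab, particles = emptyParticles(), pixels = list()))
  }
  relab <- integer(K)
  relab[keep] <- seq_along(keep)
  lab[idx] <- relab[lv]
  idx <- idx[relab[lv] > 0L]
  lv <- lab[idx]
  H <- nrow(binaryFrame)
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  cx <- (vapply(split(cols, lv), mean, numeric(1)) - 0.5) * pixelSizeUm
  cy <- (vapply(split(rows, lv), mean, numeric(1)) - 0.5) * pixelSizeUm
  areaPx <- sizes[keep]
  list(labels = lab,
       particles = data.frame(label = seq_along(keep), area_px = areaPx,
                              area_um2 = areaPx * pixelSizeUm^2,
                              centroid_x_um = as.numeric(cx),
                              centroid_y_um = as.numeric(cy)),
       pixels = split(idx, lv))
}

emptyParticles <- function() {
  data.frame(label = integer(0), area_px = integer(0), area_um2 = numeric(0),
             centroid_x_um = numeric(0), centroid_y_um = numeric(0))
}

# run-based union-find connected-component labelling
labelBinary <- function(mat, connectivity = 8) {
  stopIfNot(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  H <- nrow(mat); W <- ncol(mat)
  lab <- matrix(0L, H, W)
  v <- as.logical(mat)
  if (!any(v)) return(lab)
  # vertical runs within each column (column-major scan)
  idx <- which(v)
  isStart <- c(TRUE, diff(idx) != 1L) | ((idx - 1L) %% H == 0L)
  starts <- idx[isStart]
  ends <- c(idx[which(isStart)[-1] - 1L], idx[length(idx)])
  runCol <- ((starts - 1L) %/% H) + 1L
  runR1 <- ((starts - 1L) %% H) + 1L
  runR2 <- ((ends - 1L) %% H) + 1L
  nR <- length(starts)
  parent <- seq_len(nR)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8) 1L else 0L
  colStart <- match(seq_len(W), runCol)
  for (ci in seq_len(W - 1L)) {
    a <- colStart[ci]
    b <- colStart[ci + 1L]
    if (is.na(a) || is.na(b)) next
    aEnd <- if (ci + 1L <= W && !is.na(b)) b - 1L else nR
    bEnd <- bEndFor(colStart, ci + 1L, W, nR)
    i <- a; j <- b
    while (i <= aEnd && j <= bEnd) {
      if (runR1[j] > runR2[i] + slack) { i <- i + 1L; next }
      if (runR1[i] > runR2[j] + slack) { j <- j + 1L; next }
      ri <- findRoot(i); rj <- findRoot(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      if (runR2[i] <= runR2[j]) i <- i + 1L else j <- j + 1L
    }
  }
  roots <- vapply(seq_len(nR), findRoot, integer(1))
  labs <- match(roots, sort(unique(roots)))
  for (k in seq_len(nR)) {
    c0 <- (runCol[k] - 1L) * H
    lab[(c0 + runR1[k]):(c0 + runR2[k])] <- labs[k]
  }
  lab
}

bEndFor <- function(colStart, col, W, nR) {
  nxt <- colStart[-seq_len(col)]
  nxt <- nxt[!is.na(nxt)]
  if (length(nxt)) nxt[1] - 1L else nR
}

#' Detect particles across all frames of a dF/F0 stack
#'
#' Thresholds the stack (\code{\link{thresholdDff}}) and labels every frame
#' (\code{\link{labelParticles}}).
#'
#' @param dff a \code{\linkS4class{DffStack}}.
#' @param kSd threshold in noise SDs.
#' @param connectivity 8 or 4.
#' @param minAreaPx minimum particle area, pixels.
#' @return object of class \code{"PtclMovie"}: per-frame particle tables
#'   and pixel sets plus calibration.
#' @export
detectParticles <- function(dff, kSd = 4.5, connectivity = 8, minAreaPx = 4) {
  stopifnot(is(dff, "DffStack"))
  act <- thresholdDff(dff, kSd = kSd)
  particlesFromBinary(act, frameIntervalS = dff@frameIntervalS,
                      pixelSizeUm = dff@pixelSizeUm,
                      connectivity = connectivity, minAreaPx = minAreaPx)
}

#' Label a pre-thresholded binary stack
#'
#' @param binary logical H x W x T array.
#' @param frameIntervalS,pixelSizeUm calibration.
#' @param connectivity,minAreaPx see \code{\link{labelParticles}}.
#' @return a \code{"PtclMovie"}.
#' @export
particlesFromBinary <- function(binary, frameIntervalS, pixelSizeUm,
                                connectivity = 8, minAreaPx = 4) {
  T <- dim(binary)[3]
  frames <- vector("list", T)
  for (t in seq_len(T)) {
    lp <- labelParticles(binary[, , t], connectivity = connectivity,
                         minAreaPx = minAreaPx, pixelSizeUm = pixelSizeUm)
    frames[[t]] <- list(particles = lp$particles, pixels = lp$pixels)
  }
  structure(list(frames = frames, dims = dim(binary)[1:2],
                 frameIntervalS = frameIntervalS, pixelSizeUm = pixelSizeUm),
            class = "PtclMovie")
}

#' @export
print.PtclMovie <- function(x, ...) {
  counts <- vapply(x$frames, function(f) nrow(f$particles), integer(1))
  cat(sprintf("PtclMovie: %d frames, %d particles total (max %d/frame)\n",
              length(x$frames), sum(counts), max(counts, 0)))
  invisible(x)
}

#' Summarise PTCL activity: per-frame area/count series and track durations
#'
#' Per-frame summed particle area (um^2) and particle count, and the
#' duration of every particle track, where a track lives from frame to
#' frame while at least one pixel is shared between its particles
#' (pixel-overlap linkage).
#'
#' @param ptclMovie a \code{"PtclMovie"}.
#' @return object of class \code{"PtclSeries"}: list with \code{area_um2}
#'   and \code{count} (length-T numeric vectors), \code{track_durations_s},
#'   \code{tracks} (data.frame: track_id, first_frame, last_frame,
#'   n_frames, duration_s), and calibration fields.
#' @export
summarizePtcls <- function(ptclMovie) {
  stopifnot(inherits(ptclMovie, "PtclMovie"))
  T <- length(ptclMovie$frames)
  dt <- ptclMovie$frameIntervalS
  area <- numeric(T); count <- integer(T)
  # union-find over particle nodes for overlap tracking
  nodeFrame <- integer(0); parent <- integer(0)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  prevPix <- integer(0); prevPid <- integer(0); prevNodes <- integer(0)
  for (t in seq_len(T)) {
    fr <- ptclMovie$frames[[t]]
    np <- nrow(fr$particles)
    area[t] <- sum(fr$particles$area_um2)
    count[t] <- np
    nodes <- integer(np)
    if (np > 0) {
      base <- length(parent)
      parent <- c(parent, base + seq_len(np))
      nodeFrame <- c(nodeFrame, rep(t, np))
      nodes <- base + seq_len(np)
      if (length(prevPix) > 0) {
        for (p in seq_len(np)) {
          hit <- match(fr$pixels[[p]], prevPix)
          hit <- hit[!is.na(hit)]
          if (length(hit)) {
            for (q in unique(prevPid[hit])) {
              ra <- findRoot(nodes[p]); rb <- findRoot(prevNodes[q])
              if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
            }
          }
        }
      }
    }
    if (np > 0) {
      pl <- lengths(fr$pixels)
      prevPix <- unlist(fr$pixels, use.names = FALSE)
      prevPid <- rep.int(seq_len(np), pl)
      prevNodes <- nodes
    } else {
      prevPix <- integer(0); prevPid <- integer(0); prevNodes <- integer(0)
    }
  }
  if (length(parent)) {
    roots <- vapply(seq_along(parent), findRoot, integer(1))
    tid <- match(roots, unique(roots))
    ff <- vapply(split(nodeFrame, tid), min, numeric(1))
    lf <- vapply(split(nodeFrame, tid), max, numeric(1))
    tracks <- data.frame(track_id = seq_along(ff), first_frame = ff,
                         last_frame = lf, n_frames = lf - ff + 1,
                         duration_s = (lf - ff + 1) * dt)
  } else {
    tracks <- data.frame(track_id = integer(0), first_frame = numeric(0),
                         last_frame = numeric(0), n_frames = numeric(0),
                         duration_s = numeric(0))
  }
  structure(list(area_um2 = area, count = as.numeric(count),
                 track_durations_s = tracks$duration_s, tracks = tracks,
                 frameIntervalS = dt, pixelSizeUm = ptclMovie$pixelSizeUm),
            class = "PtclSeries")
}

#' @export
print.PtclSeries <- function(x, ...) {
  cat(sprintf(
    "PtclSeries: %d frames; mean area %.2f um2/frame, mean count %.2f/frame, %d tracks\n",
    length(x$count), mean(x$area_um2), mean(x$count), nrow(x$tracks)))
  invisible(x)
}

#' Isolate firing/initiation particles by the 70-ms rule
#'
#' A particle in frame t is an initiation iff (a) it shares no pixel with
#' any particle in frame t-1, and (b) it shares at least one pixel with a
#' particle in a strictly later frame whose start time is within
#' \code{windowMs} of frame t's start time (at 33 fps: the next 2 frames).
#'
#' @param ptclMovie a \code{"PtclMovie"}.
#' @param windowMs forward-overlap window, milliseconds.
#' @return data.frame of class \code{"Initiations"}: frame, time_s,
#'   centroid_x_um, centroid_y_um, area_um2.
#' @export
detectInitiations <- function(ptclMovie, windowMs = 70) {
  stopifnot(inherits(ptclMovie, "PtclMovie"))
  T <- length(ptclMovie$frames)
  dt <- ptclMovie$frameIntervalS
  mFwd <- floor(windowMs / 1000 / dt + 1e-9)
  pixAt <- lapply(ptclMovie$frames, function(f)
    unlist(f$pixels, use.names = FALSE))
  out <- list()
  for (t in seq_len(T)) {
    fr <- ptclMovie$frames[[t]]
    np <- nrow(fr$particles)
    if (np == 0) next
    prev <- if (t > 1) pixAt[[t - 1]] else integer(0)
    hi <- min(T, t + mFwd)
    fwdFrames <- if (hi >= t + 1L) (t + 1L):hi else integer(0)
    for (p in seq_len(np)) {
      px <- fr$pixels[[p]]
      if (length(prev) && any(px %in% prev)) next        # condition (a)
      ok <- FALSE
      for (u in fwdFrames) {
        if (length(pixAt[[u]]) && any(px %in% pixAt[[u]])) { ok <- TRUE; break }
      }
      if (!ok) next                                       # condition (b)
      out[[length(out) + 1L]] <- data.frame(
        frame = t, time_s = (t - 1) * dt,
        centroid_x_um = fr$particles$centroid_x_um[p],
        centroid_y_um = fr$particles$centroid_y_um[p],
        area_um2 = fr$particles$area_um2[p])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(0), time_s = numeric(0),
               centroid_x_um = numeric(0), centroid_y_um = numeric(0),
               area_um2 = numeric(0))
  class(res) <- c("Initiations", "data.frame")
  res
}

#' Group initiation particles into firing sites
#'
#' Greedy centroid clustering in time order: an initiation joins the
#' nearest existing site if its centroid lies within
#' \code{groupingRadiusUm} of the site centroid (a running mean over
#' members), otherwise it founds a new site. Deterministic given the input
#' order.
#'
#' @param initiations an \code{"Initiations"} data.frame.
#' @param groupingRadiusUm grouping radius, micrometers.
#' @return object of class \code{"FiringSites"}: list with \code{sites}
#'   (data.frame: site_id, x_um, y_um, n_activations, first_time_s) and
#'   \code{activations} (data.frame: site_id, frame, time_s, x_um, y_um).
#' @export
groupSites <- function(initiations, groupingRadiusUm = 5) {
  initiations <- initiations[order(initiations$time_s), ]
  sx <- numeric(0); sy <- numeric(0); sn <- integer(0)
  assign <- integer(nrow(initiations))
  for (i in seq_len(nrow(initiations))) {
    x <- initiations$centroid_x_um[i]; y <- initiations$centroid_y_um[i]
    if (length(sx)) {
      d2 <- (sx - x)^2 + (sy - y)^2
      j <- which.min(d2)
      if (d2[j] <= groupingRadiusUm^2) {
        sx[j] <- (sx[j] * sn[j] + x) / (sn[j] + 1L)
        sy[j] <- (sy[j] * sn[j] + y) / (sn[j] + 1L)
        sn[j] <- sn[j] + 1L
        assign[i] <- j
        next
      }
    }
    sx <- c(sx, x); sy <- c(sy, y); sn <- c(sn, 1L)
    assign[i] <- length(sx)
  }
  activations <- data.frame(site_id = assign,
                            frame = initiations$frame,
                            time_s = initiations$time_s,
                            x_um = initiations$centroid_x_um,
                            y_um = initiations$centroid_y_um)
  firstT <- if (length(sx)) vapply(split(activations$time_s, activations$site_id),
                                   min, numeric(1)) else numeric(0)
  sites <- data.frame(site_id = seq_along(sx), x_um = sx, y_um = sy,
                      n_activations = sn,
                      first_time_s = as.numeric(firstT))
  structure(list(sites = sites, activations = activations),
            class = "FiringSites")
}

#' @export
print.FiringSites <- function(x, ...) {
  cat(sprintf("FiringSites: %d sites, %d activations\n",
              nrow(x$sites), nrow(x$activations)))
  invisible(x)
}

#' Build a site x time occurrence map
#'
#' Boolean raster with one lane per firing site, \code{TRUE} at the frames
#' where the site initiated a transient; lanes ordered by first activation
#' time.
#'
#' @param firingSites a \code{"FiringSites"} object.
#' @param nFramesT total number of frames.
#' @param frameIntervalS seconds per frame.
#' @return an \code{\linkS4class{OccurrenceMap}}.
#' @export
buildOccurrenceMap <- function(firingSites, nFramesT, frameIntervalS) {
  stopifnot(inherits(firingSites, "FiringSites"))
  s <- firingSites$sites
  ord <- s$site_id[order(s$first_time_s, s$site_id)]
  raster <- matrix(FALSE, nrow = length(ord), ncol = nFramesT)
  a <- firingSites$activations
  lane <- match(a$site_id, ord)
  raster[cbind(lane, a$frame)] <- TRUE
  new("OccurrenceMap", raster = raster, siteIds = as.integer(ord),
      frameIntervalS = frameIntervalS)
}
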