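#' Build a spatiotemporal map along a cell axis
#'
#' For each arc-length position along the axis polyline (sampled at
#' pixel-size spacing), the map value in a frame is the mean dF/F0 over
#' the analysable pixels lying within \code{widthUm / 2} of the axis,
#' perpendicular to it — the fluorescence "across the diameter of the
#' cell" as a position x time matrix.
#'
#' @param dff a \code{\linkS4class{DffStack}}.
#' @param axisPolylineUm two-column matrix of (x_um, y_um) vertices; must
#'   lie inside the FOV.
#' @param widthUm full width of the averaging band, micrometers.
#' @param cellId integer id stored in the result.
#' @return an \code{\linkS4class{STMap}}.
#' @export
buildSTMap <- function(dff, axisPolylineUm, widthUm = 10, cellId = 1L) {
  stopifnot(is(dff, "DffStack"))
  ax <- as.matrix(axisPolylineUm)
  stopIfNot(ncol(ax) == 2 && nrow(ax) >= 2, "axis polyline needs >= 2 (x, y) vertices")
  stopIfNot(widthUm > 0, "widthUm must be > 0")
  px <- dff@pixelSizeUm
  H <- dim(dff@data)[1]; W <- dim(dff@data)[2]; T <- dim(dff@data)[3]
  if (any(ax[, 1] < 0 | ax[, 1] > W * px | ax[, 2] < 0 | ax[, 2] > H * px))
    stop("axis polyline lies outside the image")
  xs <- rep((seq_len(W) - 0.5) * px, each = H)
  ys <- rep((seq_len(H) - 0.5) * px, times = W)
  okMask <- as.vector(dff@mask)
  bestPerp <- rep(Inf, H * W)
  bestArc <- rep(NA_real_, H * W)
  cum <- 0
  for (s in seq_len(nrow(ax) - 1)) {
    a <- ax[s, ]; b <- ax[s + 1, ]
    len <- sqrt(sum((b - a)^2))
    if (len < 1e-9) next
    dv <- (b - a) / len
    tproj <- (xs - a[1]) * dv[1] + (ys - a[2]) * dv[2]
    perp <- abs(-(xs - a[1]) * dv[2] + (ys - a[2]) * dv[1])
    sel <- tproj >= 0 & tproj <= len & perp <= widthUm / 2 & perp < bestPerp
    bestPerp[sel] <- perp[sel]
    bestArc[sel] <- cum + tproj[sel]
    cum <- cum + len
  }
  use <- which(is.finite(bestArc) & okMask)
  stopIfNot(length(use) > 0, "no analysable pixels within the axis band")
  bin <- pmax(1L, ceiling(bestArc[use] / px))
  m <- dff@data
  dim(m) <- c(H * W, T)
  grp <- factor(bin, levels = sort(unique(bin)))
  sums <- rowsum(m[use, , drop = FALSE], grp)
  counts <- as.integer(table(grp))
  mat <- sums / counts
  positions <- (as.integer(levels(grp)) - 0.5) * px
  new("STMap", matrix = unname(mat), axisPolylineUm = ax,
      positionsUm = positions, cellId = as.integer(cellId),
      frameIntervalS = dff@frameIntervalS, pixelSizeUm = px)
}

#' Segment calcium transient events from a spatiotemporal map
#'
#' Supra-threshold connected regions of the map (threshold =
#' \code{thresholdFraction} x the map's robust maximum, i.e. half-maximum
#' by default) become events. For each event, the amplitude is the region
#' maximum, and the duration and spatial spread are the temporal and
#' spatial extents at half of that event's own maximum, measured on the
#' profile of row-wise/column-wise maxima walked out from the peak (so a
#' dimmer event is not clipped by the map-wide threshold). Area is the
#' supra-threshold cell count x (um x s). Regions separated by at least
#' one sub-threshold frame are distinct.
#'
#' @param stmap an \code{\linkS4class{STMap}}.
#' @param thresholdFraction fraction of the map robust maximum (99.5th
#'   percentile) used for region detection; default 0.5.
#' @param minCells minimum region size in map cells.
#' @return data.frame with columns cell_id, onset_s, peak_s, end_s,
#'   duration_s, amplitude_dff, spread_um, area_um_s, sorted by onset.
#' @export
segmentEvents <- function(stmap, thresholdFraction = 0.5, minCells = 4) {
  stopifnot(is(stmap, "STMap"))
  M <- stmap@matrix
  dtS <- stmap@frameIntervalS
  dxUm <- stmap@pixelSizeUm
  empty <- data.frame(cell_id = integer(0), onset_s = numeric(0),
                      peak_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), amplitude_dff = numeric(0),
                      spread_um = numeric(0), area_um_s = numeric(0))
  rmax <- robustMax(M)
  if (!is.finite(rmax) || rmax <= 0) return(empty)
  thr <- thresholdFraction * rmax
  lab <- labelBinary(M > thr, connectivity = 8)
  K <- max(lab)
  if (K == 0) return(empty)
  out <- list()
  for (k in seq_len(K)) {
    idx <- which(lab == k)
    if (length(idx) < minCells) next
    amp <- max(M[idx])
    half <- amp / 2
    pk <- idx[which.max(M[idx])]
    pr <- ((pk - 1) %% nrow(M)) + 1
    pc <- ((pk - 1) %/% nrow(M)) + 1
    rows <- ((idx - 1) %% nrow(M)) + 1
    cols <- ((idx - 1) %/% nrow(M)) + 1
    # temporal profile: per-column max over the event's rows
    rr <- range(rows)
    tprof <- apply(M[rr[1]:rr[2], , drop = FALSE], 2, max)
    cspan <- walkExtent(tprof, pc, half)
    # spatial profile: per-row max over the event's columns
    cc <- range(cols)
    sprof <- apply(M[, cc[1]:cc[2], drop = FALSE], 1, max)
    rspan <- walkExtent(sprof, pr, half)
    onset <- (cspan[1] - 1) * dtS
    end <- cspan[2] * dtS
    out[[length(out) + 1L]] <- data.frame(
      cell_id = stmap@cellId,
      onset_s = onset, peak_s = min(max((pc - 0.5) * dtS, onset), end),
      end_s = end, duration_s = end - onset,
      amplitude_dff = amp,
      spread_um = (rspan[2] - rspan[1] + 1) * dxUm,
      area_um_s = length(idx) * dxUm * dtS)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$onset_s), ]
  rownames(res) <- NULL
  res
}

# contiguous index span around `center` where profile >= level
walkExtent <- function(prof, center, level) {
  lo <- center
  while (lo > 1 && prof[lo - 1] >= level) lo <- lo - 1
  hi <- center
  while (hi < length(prof) && prof[hi + 1] >= level) hi <- hi + 1
  c(lo, hi)
}

#' Percentage overlap between two spatiotemporal maps
#'
#' Binarises both maps at \code{thresholdFraction} of their own robust
#' maxima and returns the Jaccard overlap, 100 x |A and B| / |A or B|
#' (0 when the union is empty).
#'
#' @param stmapA,stmapB \code{\linkS4class{STMap}}s (or plain matrices) of
#'   equal dimensions.
#' @param thresholdFraction binarisation fraction.
#' @return overlap percentage.
#' @export
overlapPercentage <- function(stmapA, stmapB, thresholdFraction = 0.5) {
  A <- if (is(stmapA, "STMap")) stmapA@matrix else as.matrix(stmapA)
  B <- if (is(stmapB, "STMap")) stmapB@matrix else as.matrix(stmapB)
  stopIfNot(identical(dim(A), dim(B)), "maps must have identical shapes")
  a <- A > thresholdFraction * robustMax(A)
  b <- B > thresholdFraction * robustMax(B)
  u <- sum(a | b)
  if (u == 0) return(0)
  100 * sum(a & b) / u
}

#' Peak-to-peak firing intervals of a trace
#'
#' Detects local maxima above \code{thresholdFraction} of the trace's
#' robust maximum with a minimum peak separation, and returns successive
#' peak-to-peak intervals in seconds. An \code{\linkS4class{STMap}} input
#' is reduced to its column-mean trace first.
#'
#' @param x numeric trace or an \code{STMap}.
#' @param frameIntervalS seconds per sample (taken from the map when
#'   \code{x} is an \code{STMap}).
#' @param minSeparationS minimum separation between accepted peaks.
#' @param thresholdFraction peak height threshold.
#' @return numeric vector of intervals (empty when < 2 peaks).
#' @export
peakIntervals <- function(x, frameIntervalS = NULL, minSeparationS = 1,
                          thresholdFraction = 0.5) {
  if (is(x, "STMap")) {
    frameIntervalS <- x@frameIntervalS
    x <- colMeans(x@matrix)
  }
  stopIfNot(!is.null(frameIntervalS), "frameIntervalS required for a plain trace")
  n <- length(x)
  if (n < 3) return(numeric(0))
  thr <- thresholdFraction * robustMax(x)
  if (!is.finite(thr)) return(numeric(0))
  above <- x >= thr
  if (all(above) || !any(above)) return(numeric(0))
  # one peak per contiguous supra-threshold segment: rhythmic transients
  # are plateau-shaped, so bare local maxima would split single events
  d <- diff(c(FALSE, above))
  starts <- which(d == 1)
  ends <- which(diff(c(above, FALSE)) == -1)
  peaks <- vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(x[seg])]
  }, integer(1))
  # enforce the minimum separation (drop the lower of close pairs)
  sep <- minSeparationS / frameIntervalS
  ord <- peaks[order(x[peaks], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= sep)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  if (length(kept) < 2) return(numeric(0))
  diff((kept - 1) * frameIntervalS)
}
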