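#' Detect cell bodies in a calibrated still image
#'
#' Gaussian-smoothed local-maximum detection: the image is smoothed,
#' thresholded at \code{thresholdFraction} of its background-to-peak
#' excursion, and supra-threshold local maxima are taken as soma
#' candidates; maxima closer than \code{minDiameterUm} are merged (the
#' brighter one wins). Positions are refined by a 3 x 3
#' intensity-weighted centroid.
#'
#' @param image numeric matrix (still image).
#' @param pixelSizeUm micrometers per pixel.
#' @param minDiameterUm minimum soma diameter; closer maxima merge.
#' @param smoothSigmaUm smoothing SD, micrometers.
#' @param thresholdFraction detection threshold as a fraction of the
#'   background-to-peak excursion.
#' @return data.frame: x_um, y_um, intensity (empty for a blank image).
#' @export
detectCellBodies <- function(image, pixelSizeUm, minDiameterUm = 15,
                             smoothSigmaUm = 3, thresholdFraction = 0.3) {
  stopifnot(is.matrix(image))
  if (max(image) - min(image) < 1e-12)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  sgPx <- smoothSigmaUm / pixelSizeUm
  hw <- max(1L, ceiling(2.5 * sgPx))
  g <- stats::dnorm(seq(-hw, hw), sd = sgPx)
  K <- outer(g, g); K <- K / sum(K)
  sm <- convolve2(image, K)
  bg <- stats::median(sm)
  thr <- bg + thresholdFraction * (max(sm) - bg)
  H <- nrow(sm); W <- ncol(sm)
  isMax <- sm >= thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- matrix(-Inf, H, W)
    dstR <- max(1, 1 + di):min(H, H + di); srcR <- dstR - di
    dstC <- max(1, 1 + dj):min(W, W + dj); srcC <- dstC - dj
    shifted[dstR, dstC] <- sm[srcR, srcC]
    isMax <- isMax & (sm >= shifted)
  }
  idx <- which(isMax)
  if (!length(idx))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  rows <- ((idx - 1) %% H) + 1
  cols <- ((idx - 1) %/% H) + 1
  ord <- order(sm[idx], decreasing = TRUE)
  keptR <- numeric(0); keptC <- numeric(0); keptI <- numeric(0)
  minD2 <- (minDiameterUm / pixelSizeUm)^2
  for (k in ord) {
    r <- rows[k]; c <- cols[k]
    if (length(keptR) && min((keptR - r)^2 + (keptC - c)^2) < minD2) next
    # subpixel refinement: intensity-weighted 3x3 centroid
    rr <- max(1, r - 1):min(H, r + 1)
    cc <- max(1, c - 1):min(W, c + 1)
    wts <- sm[rr, cc] - min(sm[rr, cc])
    if (sum(wts) > 0) {
      r <- sum(outer(rr, rep(1, length(cc))) * wts) / sum(wts)
      c <- sum(outer(rep(1, length(rr)), cc) * wts) / sum(wts)
    }
    keptR <- c(keptR, r); keptC <- c(keptC, c)
    keptI <- c(keptI, sm[rows[k], cols[k]])
  }
  data.frame(x_um = (keptC - 0.5) * pixelSizeUm,
             y_um = (keptR - 0.5) * pixelSizeUm,
             intensity = keptI)
}

# border-renormalised 2-D convolution of a single frame
convolve2 <- function(img, K) {
  H <- nrow(img); W <- ncol(img)
  hw <- (nrow(K) - 1) %/% 2
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  for (i in seq(-hw, hw)) for (j in seq(-hw, hw)) {
    w <- K[i + hw + 1, j + hw + 1]
    dstR <- max(1, 1 + i):min(H, H + i); srcR <- dstR - i
    dstC <- max(1, 1 + j):min(W, W + j); srcC <- dstC - j
    num[dstR, dstC] <- num[dstR, dstC] + w * img[srcR, srcC]
    den[dstR, dstC] <- den[dstR, dstC] + w
  }
  num / den
}

#' Cell-body density
#'
#' @param positions data.frame (or matrix) of detected positions.
#' @param areaMm2 analysed area in mm^2 (> 0).
#' @return cells per mm^2.
#' @export
cellDensity <- function(positions, areaMm2) {
  stopIfNot(areaMm2 > 0, "areaMm2 must be > 0")
  nrow(as.data.frame(positions)) / areaMm2
}

#' Mean minimum (nearest-neighbour) separation between cell bodies
#'
#' Mean over cells of the Euclidean distance to the nearest other cell.
#' When the FOV is supplied, cells within \code{borderMarginUm} of the
#' border are excluded as focal points (their true nearest neighbour may
#' lie outside the image) but still serve as neighbours.
#'
#' @param positions data.frame with x_um, y_um (or a 2-column matrix);
#'   at least 2 cells.
#' @param fovUm optional \code{c(width, height)} in micrometers.
#' @param borderMarginUm border exclusion margin for focal points.
#' @return mean nearest-neighbour distance, micrometers.
#' @export
meanMinSeparation <- function(positions, fovUm = NULL, borderMarginUm = 0) {
  p <- as.data.frame(positions)
  if (is.null(p$x_um)) { colnames(p)[1:2] <- c("x_um", "y_um") }
  n <- nrow(p)
  stopIfNot(n >= 2, "separation requires at least 2 cells")
  D <- as.matrix(stats::dist(p[, c("x_um", "y_um")]))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  focal <- rep(TRUE, n)
  if (!is.null(fovUm) && borderMarginUm > 0) {
    focal <- p$x_um >= borderMarginUm & p$x_um <= fovUm[1] - borderMarginUm &
             p$y_um >= borderMarginUm & p$y_um <= fovUm[2] - borderMarginUm
    if (!any(focal)) focal <- rep(TRUE, n)
  }
  mean(nn[focal])
}

#' Generate a synthetic cell-body field
#'
#' Hard-core random placement at the configured density; optionally the
#' positions (and FOV) are affinely rescaled about the field centre so
#' the ground-truth mean nearest-neighbour distance equals
#' \code{rescaleToNNUm} (density and nearest-neighbour separation cannot
#' both be chosen freely under a simple point process, so
#' separation-recovery studies use this mode).
#'
#' @param config a \code{\link{generatorConfig}} (density, FOV, hard-core
#'   separation).
#' @param seed RNG seed.
#' @param rescaleToNNUm target mean nearest-neighbour distance, or
#'   \code{NULL} for no rescaling.
#' @return list with \code{positions} (data.frame x_um, y_um),
#'   \code{fov_um}, \code{area_mm2}.
#' @export
generateCellField <- function(config, seed = config$seed,
                              rescaleToNNUm = NULL) {
  stopifnot(inherits(config, "GeneratorConfig"))
  fw <- config$fov_width_um; fh <- config$fov_height_um
  pos <- withSeed(seed, {
    n <- stats::rpois(1, config$cell_density_per_mm2 * fw * fh / 1e6)
    placeHardCore(n, fw, fh, config$min_separation_um)
  })
  positions <- data.frame(x_um = pos$x, y_um = pos$y)
  fov <- c(width = fw, height = fh)
  if (!is.null(rescaleToNNUm) && nrow(positions) >= 2) {
    cur <- meanMinSeparation(positions)
    s <- rescaleToNNUm / cur
    cx <- fw / 2; cy <- fh / 2
    positions$x_um <- cx * s + (positions$x_um - cx) * s
    positions$y_um <- cy * s + (positions$y_um - cy) * s
    fov <- fov * s
  }
  list(positions = positions, fov_um = fov,
       area_mm2 = unname(fov[1] * fov[2] / 1e6))
}

#' Render a synthetic still image of a cell field
#'
#' Each soma is a Gaussian blob on a dim background with additive noise:
#' the input for cell-body detection recovery studies.
#'
#' @param field output of \code{\link{generateCellField}}.
#' @param pixelSizeUm micrometers per pixel.
#' @param somaSigmaUm soma blob SD, micrometers.
#' @param amplitude blob peak intensity.
#' @param noiseSd additive Gaussian noise SD.
#' @param seed RNG seed for the noise.
#' @return numeric image matrix.
#' @export
renderFieldImage <- function(field, pixelSizeUm = 2, somaSigmaUm = 4,
                             amplitude = 1, noiseSd = 0.02, seed = 1) {
  H <- round(field$fov_um[["height"]] / pixelSizeUm)
  W <- round(field$fov_um[["width"]] / pixelSizeUm)
  img <- matrix(0, H, W)
  xc <- (seq_len(W) - 0.5) * pixelSizeUm
  yc <- (seq_len(H) - 0.5) * pixelSizeUm
  for (i in seq_len(nrow(field$positions))) {
    gx <- exp(-(xc - field$positions$x_um[i])^2 / (2 * somaSigmaUm^2))
    gy <- exp(-(yc - field$positions$y_um[i])^2 / (2 * somaSigmaUm^2))
    img <- img + amplitude * outer(gy, gx)
  }
  if (noiseSd > 0)
    img <- img + withSeed(seed, matrix(stats::rnorm(H * W, sd = noiseSd), H, W))
  img
}

#' Summarise the geometry of a detected cell field
#'
#' @param positions data.frame of positions (x_um, y_um).
#' @param areaMm2 analysed area, mm^2.
#' @param fovUm,borderMarginUm passed to \code{\link{meanMinSeparation}}.
#' @return list of class \code{"GeometryResult"}: n_cells,
#'   density_per_mm2, mean_min_separation_um, positions_um.
#' @export
geometrySummary <- function(positions, areaMm2, fovUm = NULL,
                            borderMarginUm = 0) {
  n <- nrow(positions)
  structure(list(
    n_cells = n,
    density_per_mm2 = cellDensity(positions, areaMm2),
    mean_min_separation_um = if (n >= 2)
      meanMinSeparation(positions, fovUm, borderMarginUm) else NA_real_,
    positions_um = positions), class = "GeometryResult")
}

#' @export
print.GeometryResult <- function(x, ...) {
  cat(sprintf(
    "GeometryResult: %d cells, %.1f cells/mm2, mean min separation %.1f um\n",
    x$n_cells, x$density_per_mm2, x$mean_min_separation_um))
  invisible(x)
}
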