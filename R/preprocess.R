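#' Rigid translation registration of a movie
#'
#' Estimates a per-frame x/y drift against the temporal-mean image by
#' maximising the image cross-correlation (computed by FFT), refines the
#' peak to subpixel precision by parabolic interpolation, and shifts each
#' frame back by the rounded shift (edge fill = frame median). The
#' temporal-mean reference is robust to sparse transient events.
#'
#' @param movie a \code{\linkS4class{MovieStack}} with at least 2 frames.
#' @return list with \code{movie} (stabilised \code{MovieStack}) and
#'   \code{driftUm}, a data.frame (frame, dx_um, dy_um) of the estimated
#'   drift of each frame relative to the reference (subpixel, micrometers).
#' @details An all-constant movie yields zero shifts. The drift magnitude
#'   \code{sqrt(dx^2 + dy^2)} doubles as an optical tissue-displacement
#'   proxy for dual-channel latency analysis.
#' @export
registerTranslation <- function(movie) {
  stopifnot(is(movie, "MovieStack"))
  d <- movie@data
  T <- dim(d)[3]
  stopIfNot(T >= 2, "registration requires at least 2 frames")
  H <- dim(d)[1]; W <- dim(d)[2]
  ref <- rowMeans(d, dims = 2)
  refC <- ref - mean(ref)
  Fr <- stats::fft(refC)
  dx <- numeric(T); dy <- numeric(T)
  out <- d
  for (t in seq_len(T)) {
    fr <- d[, , t]
    frC <- fr - mean(fr)
    cc <- Re(stats::fft(stats::fft(frC) * Conj(Fr), inverse = TRUE))
    pk <- which.max(cc)
    pr <- ((pk - 1) %% H) + 1
    pc <- ((pk - 1) %/% H) + 1
    sy <- wrapShift(pr - 1L, H)
    sx <- wrapShift(pc - 1L, W)
    # subpixel refinement along each axis
    sy <- sy + parabolicOffset(
      cc[wrapIndex(pr - 1L, H), pc], cc[pr, pc], cc[wrapIndex(pr + 1L, H), pc])
    sx <- sx + parabolicOffset(
      cc[pr, wrapIndex(pc - 1L, W)], cc[pr, pc], cc[pr, wrapIndex(pc + 1L, W)])
    # cc peak at (sy, sx) means the frame is displaced by +(sy, sx)
    dy[t] <- sy; dx[t] <- sx
    if (round(sy) != 0 || round(sx) != 0)
      out[, , t] <- shiftFrame(fr, -round(sy), -round(sx))
  }
  px <- movie@pixelSizeUm
  stab <- new("MovieStack", data = out, frameIntervalS = movie@frameIntervalS,
              pixelSizeUm = px, channelLabel = movie@channelLabel)
  list(movie = stab,
       driftUm = data.frame(frame = seq_len(T), dx_um = dx * px, dy_um = dy * px))
}

wrapShift <- function(s, n) if (s > n / 2) s - n else s
wrapIndex <- function(i, n) ((i - 1L) %% n) + 1L

parabolicOffset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  off <- 0.5 * (ym - yp) / den
  if (abs(off) > 1) 0 else off
}

# integer shift with constant fill = frame median
shiftFrame <- function(fr, sy, sx) {
  H <- nrow(fr); W <- ncol(fr)
  out <- matrix(stats::median(fr), H, W)
  srcR <- seq_len(H) - sy
  srcC <- seq_len(W) - sx
  okR <- srcR >= 1 & srcR <= H
  okC <- srcC >= 1 & srcC <= W
  out[which(okR), which(okC)] <- fr[srcR[okR], srcC[okC]]
  out
}

#' Drift magnitude trace
#'
#' @param driftUm drift data.frame from \code{\link{registerTranslation}}.
#' @return numeric vector of per-frame drift magnitudes in micrometers.
#' @export
driftMagnitude <- function(driftUm) {
  sqrt(driftUm$dx_um^2 + driftUm$dy_um^2)
}

#' Estimate the scalar image background
#'
#' Mean of the darkest 1\% of pixels of the temporal-mean image: in a
#' calcium-imaging field this samples indicator-free regions (camera offset
#' plus autofluorescence haze).
#'
#' @param movie a \code{\linkS4class{MovieStack}}.
#' @param fraction darkest fraction of pixels to average (default 0.01).
#' @return scalar background estimate in raw intensity units.
#' @export
estimateBackground <- function(movie, fraction = 0.01) {
  stopifnot(is(movie, "MovieStack"))
  mImg <- rowMeans(movie@data, dims = 2)
  v <- sort(as.vector(mImg))
  k <- max(1L, ceiling(fraction * length(v)))
  mean(v[seq_len(k)])
}

#' Subtract the scalar background from a movie
#'
#' @param movie a \code{\linkS4class{MovieStack}}.
#' @param background optional scalar; estimated with
#'   \code{\link{estimateBackground}} when missing.
#' @return a \code{MovieStack} with the background removed (floored at 0).
#' @export
subtractBackground <- function(movie, background = NULL) {
  stopifnot(is(movie, "MovieStack"))
  if (is.null(background)) background <- estimateBackground(movie)
  d <- movie@data - background
  d[d < 0] <- 0
  new("MovieStack", data = d, frameIntervalS = movie@frameIntervalS,
      pixelSizeUm = movie@pixelSizeUm, channelLabel = movie@channelLabel)
}

#' Per-frame 2-D Gaussian smoothing
#'
#' Convolves each frame with a unit-sum Gaussian kernel truncated to a
#' \code{windowUm}-square window (default 1.5 x 1.5 um) with standard
#' deviation \code{sigmaPx} pixels (default 1.0). Near borders the kernel
#' is renormalised over the in-image support, so constant frames are exact
#' fixed points everywhere.
#'
#' @param movie a \code{\linkS4class{MovieStack}}.
#' @param windowUm kernel window side length, micrometers.
#' @param sigmaPx Gaussian standard deviation in pixels.
#' @return smoothed \code{MovieStack}.
#' @export
gaussianSmooth <- function(movie, windowUm = 1.5, sigmaPx = 1.0) {
  stopifnot(is(movie, "MovieStack"))
  stopIfNot(windowUm > 0, "windowUm must be > 0")
  px <- movie@pixelSizeUm
  wpx <- round(windowUm / px)
  if (wpx < 2) {
    warning("smoothing window smaller than one pixel; returning movie unchanged")
    return(movie)
  }
  if (wpx %% 2 == 0) wpx <- wpx + 1  # odd window centred on the pixel
  hw <- (wpx - 1) %/% 2
  g <- stats::dnorm(seq(-hw, hw), sd = sigmaPx)
  K <- outer(g, g)
  K <- K / sum(K)
  d <- movie@data
  H <- dim(d)[1]; W <- dim(d)[2]
  num <- array(0, dim = dim(d))
  den <- matrix(0, H, W)
  for (i in seq(-hw, hw)) for (j in seq(-hw, hw)) {
    w <- K[i + hw + 1, j + hw + 1]
    dstR <- max(1, 1 + i):min(H, H + i)
    srcR <- dstR - i
    dstC <- max(1, 1 + j):min(W, W + j)
    srcC <- dstC - j
    num[dstR, dstC, ] <- num[dstR, dstC, , drop = FALSE] +
      w * d[srcR, srcC, , drop = FALSE]
    den[dstR, dstC] <- den[dstR, dstC] + w
  }
  num <- num / as.vector(den)  # den recycles over frames (column-major)
  new("MovieStack", data = num, frameIntervalS = movie@frameIntervalS,
      pixelSizeUm = movie@pixelSizeUm, channelLabel = movie@channelLabel)
}

#' Smoothing kernel used by \code{\link{gaussianSmooth}}
#'
#' Exposed so the kernel can be inspected or verified directly.
#' @param pixelSizeUm micrometers per pixel.
#' @param windowUm window side, micrometers.
#' @param sigmaPx standard deviation, pixels.
#' @return unit-sum kernel matrix, or \code{NULL} if the window is smaller
#'   than one pixel.
#' @export
smoothingKernel <- function(pixelSizeUm, windowUm = 1.5, sigmaPx = 1.0) {
  wpx <- round(windowUm / pixelSizeUm)
  if (wpx < 2) return(NULL)
  if (wpx %% 2 == 0) wpx <- wpx + 1
  hw <- (wpx - 1) %/% 2
  g <- stats::dnorm(seq(-hw, hw), sd = sigmaPx)
  K <- outer(g, g)
  K / sum(K)
}

#' Pixelwise dF/F0 normalisation
#'
#' The baseline \eqn{F_0} is the per-pixel temporal percentile (default
#' 10th): at the reference pacemaker statistics (14.9 waves/min lasting
#' ~2 s) every pixel is quiescent more than 10\% of the time, so the
#' percentile lands on baseline frames. Pixels whose baseline falls below
#' \code{f0FloorFrac} of the baseline image's robust maximum are
#' indicator-free background (dark in every frame): their floored,
#' positively skewed noise cannot be normalised meaningfully, so they are
#' masked out of all downstream analysis.
#'
#' @param movie a \code{\linkS4class{MovieStack}} (non-negative).
#' @param f0Percentile temporal percentile defining F0, in (0, 1).
#' @param f0FloorFrac baseline floor as a fraction of the robust maximum
#'   (99.9th percentile) of the F0 image.
#' @param provenance character vector describing prior steps.
#' @return a \code{\linkS4class{DffStack}}.
#' @export
computeDff <- function(movie, f0Percentile = 0.10, f0FloorFrac = 0.05,
                       provenance = character(0)) {
  stopifnot(is(movie, "MovieStack"))
  d <- movie@data
  if (max(d) <= 0) stop("no baseline signal (movie is identically zero)")
  H <- dim(d)[1]; W <- dim(d)[2]; T <- dim(d)[3]
  m <- d
  dim(m) <- c(H * W, T)
  f0 <- rowQuantile(m, f0Percentile)
  floorVal <- f0FloorFrac * robustMax(f0, 0.999)
  mask <- f0 > floorVal
  dff <- (m - f0) / ifelse(mask, f0, 1)
  dff[!mask, ] <- 0
  dim(dff) <- c(H, W, T)
  new("DffStack", data = dff,
      f0Image = matrix(f0, H, W), mask = matrix(mask, H, W),
      frameIntervalS = movie@frameIntervalS, pixelSizeUm = movie@pixelSizeUm,
      channelLabel = movie@channelLabel, f0Percentile = f0Percentile,
      provenance = c(provenance, sprintf("dff(f0=p%g)", 100 * f0Percentile)))
}

# row-wise type-7 quantile via partial sorting
rowQuantile <- function(m, p) {
  T <- ncol(m)
  if (T == 1L) return(m[, 1])
  h <- (T - 1) * p + 1
  lo <- floor(h); frac <- h - lo
  idx <- if (frac > 0) c(lo, lo + 1L) else lo
  apply(m, 1L, function(x) {
    x <- sort.int(x, partial = idx)
    if (frac > 0) x[lo] + frac * (x[lo + 1L] - x[lo]) else x[lo]
  })
}

#' Full preprocessing pipeline: stabilise, background-subtract, smooth,
#' normalise
#'
#' Applies \code{\link{registerTranslation}} (optional),
#' \code{\link{subtractBackground}}, \code{\link{gaussianSmooth}} and
#' \code{\link{computeDff}} in the standard order.
#'
#' @param movie a \code{\linkS4class{MovieStack}}.
#' @param register run rigid registration first (skip for movies known to
#'   be stationary).
#' @param windowUm,sigmaPx smoothing parameters.
#' @param f0Percentile baseline percentile.
#' @return list with \code{dff} (a \code{DffStack}) and \code{driftUm}
#'   (drift table, or \code{NULL} when \code{register = FALSE}).
#' @export
preprocessMovie <- function(movie, register = TRUE, windowUm = 1.5,
                            sigmaPx = 1.0, f0Percentile = 0.10) {
  prov <- character(0)
  drift <- NULL
  if (register) {
    reg <- registerTranslation(movie)
    movie <- reg$movie
    drift <- reg$driftUm
    prov <- c(prov, "registered")
  }
  movie <- subtractBackground(movie)
  prov <- c(prov, "background-subtracted")
  movie <- gaussianSmooth(movie, windowUm = windowUm, sigmaPx = sigmaPx)
  prov <- c(prov, sprintf("smoothed(%gum,sd%gpx)", windowUm, sigmaPx))
  dff <- computeDff(movie, f0Percentile = f0Percentile, provenance = prov)
  list(dff = dff, driftUm = drift)
}
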