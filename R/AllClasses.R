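#' @import methods
NULL

#' MovieStack: a calibrated fluorescence movie
#'
#' Container for a time-lapse fluorescence recording, stored as an
#' \code{H x W x T} array of non-negative intensities together with the
#' temporal and spatial calibration needed to express results in seconds
#' and micrometers.
#'
#' @slot data numeric array, dim \code{c(H, W, T)}; rows index y, columns x.
#' @slot frameIntervalS seconds between consecutive frames.
#' @slot pixelSizeUm micrometers per pixel (square pixels).
#' @slot channelLabel free-text channel name, e.g. \code{"ICC"} or
#'   \code{"SMC"}.
#'
#' @details Frame \code{t} spans real time \code{[(t-1), t) *
#' frameIntervalS}; the centre of pixel \code{(r, c)} sits at
#' \code{((c - 0.5), (r - 0.5)) * pixelSizeUm} in (x, y) micrometers.
#'
#' @export
setClass("MovieStack",
  representation(
    data          = "array",
    frameIntervalS = "numeric",
    pixelSizeUm   = "numeric",
    channelLabel  = "character"
  ),
  prototype(channelLabel = "ICC")
)

setValidity("MovieStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be an H x W x T array")
  if (dim(d)[3] < 1L) return("movie must contain at least one frame (T >= 1)")
  if (length(object@frameIntervalS) != 1L || object@frameIntervalS <= 0)
    return("frameIntervalS must be a single positive number")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  if (anyNA(d)) return("data must not contain NA")
  TRUE
})

#' DffStack: a movie normalised to per-pixel baseline
#'
#' Result of \code{\link{computeDff}}: pixelwise
#' \eqn{\Delta F/F_0 = (F - F_0)/F_0} values plus the baseline image
#' \eqn{F_0} and an analysis mask for pixels whose baseline was too dim to
#' normalise.
#'
#' @slot data numeric array of dF/F0 values, dim \code{c(H, W, T)}.
#' @slot f0Image per-pixel baseline \code{H x W} matrix.
#' @slot mask logical \code{H x W} matrix; \code{TRUE} where the pixel is
#'   analysable (baseline above floor).
#' @slot frameIntervalS,pixelSizeUm,channelLabel calibration carried over
#'   from the source \code{MovieStack}.
#' @slot f0Percentile temporal percentile (in (0,1)) that defined F0; used
#'   downstream to de-bias noise statistics of the baseline.
#' @slot provenance character vector of preprocessing steps applied before
#'   normalisation.
#'
#' @export
setClass("DffStack",
  representation(
    data          = "array",
    f0Image       = "matrix",
    mask          = "matrix",
    frameIntervalS = "numeric",
    pixelSizeUm   = "numeric",
    channelLabel  = "character",
    f0Percentile  = "numeric",
    provenance    = "character"
  ),
  prototype(f0Percentile = 0.10)
)

setValidity("DffStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be an H x W x T array")
  if (!identical(dim(object@f0Image), dim(d)[1:2]))
    return("f0Image must match the movie's spatial dimensions")
  if (!identical(dim(object@mask), dim(d)[1:2]))
    return("mask must match the movie's spatial dimensions")
  if (any(object@f0Image[object@mask] <= 0))
    return("f0Image must be positive at every analysed (masked-in) pixel")
  TRUE
})

#' STMap: spatiotemporal map along a cell axis
#'
#' Position x time matrix of dF/F0 averaged across the diameter of a cell,
#' sampled along an axis polyline at pixel-size spacing.
#'
#' @slot matrix numeric matrix, rows = axis positions, columns = frames.
#' @slot axisPolylineUm two-column matrix of (x, y) axis vertices, um.
#' @slot positionsUm arc-length coordinate of each row, um.
#' @slot cellId integer cell identifier.
#' @slot frameIntervalS,pixelSizeUm calibration (row spacing = pixelSizeUm,
#'   column spacing = frameIntervalS).
#'
#' @export
setClass("STMap",
  representation(
    matrix        = "matrix",
    axisPolylineUm = "matrix",
    positionsUm   = "numeric",
    cellId        = "integer",
    frameIntervalS = "numeric",
    pixelSizeUm   = "numeric"
  )
)

setValidity("STMap", function(object) {
  if (nrow(object@matrix) != length(object@positionsUm))
    return("one arc-length position per matrix row required")
  TRUE
})

#' OccurrenceMap: site x time activation raster
#'
#' Boolean raster with one lane per firing site and one column per frame;
#' \code{TRUE} marks the frames at which the site initiated a transient.
#' Lanes are ordered by each site's first activation time.
#'
#' @slot raster logical matrix, sites x frames.
#' @slot siteIds integer site ids, one per lane, in lane order.
#' @slot frameIntervalS seconds per column.
#'
#' @export
setClass("OccurrenceMap",
  representation(
    raster        = "matrix",
    siteIds       = "integer",
    frameIntervalS = "numeric"
  )
)

setValidity("OccurrenceMap", function(object) {
  if (nrow(object@raster) != length(object@siteIds))
    return("one siteId per raster lane required")
  if (nrow(object@raster) > 0 && !is.logical(object@raster))
    return("raster must be logical")
  TRUE
})

# ---- accessors ----

#' @rdname MovieStack-class
#' @param object a \code{MovieStack} or \code{DffStack}.
#' @export
setGeneric("movieData", function(object) standardGeneric("movieData"))

#' @rdname MovieStack-class
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname MovieStack-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname MovieStack-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname MovieStack-class
#' @export
setMethod("movieData", "MovieStack", function(object) object@data)
#' @rdname MovieStack-class
#' @export
setMethod("movieData", "DffStack", function(object) object@data)
#' @rdname MovieStack-class
#' @export
setMethod("frameInterval", "MovieStack", function(object) object@frameIntervalS)
#' @rdname MovieStack-class
#' @export
setMethod("frameInterval", "DffStack", function(object) object@frameIntervalS)
#' @rdname MovieStack-class
#' @export
setMethod("pixelSize", "MovieStack", function(object) object@pixelSizeUm)
#' @rdname MovieStack-class
#' @export
setMethod("pixelSize", "DffStack", function(object) object@pixelSizeUm)
#' @rdname MovieStack-class
#' @export
setMethod("nFrames", "MovieStack", function(object) dim(object@data)[3])
#' @rdname MovieStack-class
#' @export
setMethod("nFrames", "DffStack", function(object) dim(object@data)[3])

#' @rdname DffStack-class
#' @param object a \code{DffStack}.
#' @export
setGeneric("f0Image", function(object) standardGeneric("f0Image"))
#' @rdname DffStack-class
#' @export
setMethod("f0Image", "DffStack", function(object) object@f0Image)

#' @rdname STMap-class
#' @param object an \code{STMap}.
#' @export
setGeneric("stmapMatrix", function(object) standardGeneric("stmapMatrix"))
#' @rdname STMap-class
#' @export
setMethod("stmapMatrix", "STMap", function(object) object@matrix)

#' @rdname OccurrenceMap-class
#' @param object an \code{OccurrenceMap}.
#' @export
setGeneric("occurrenceRaster", function(object) standardGeneric("occurrenceRaster"))
#' @rdname OccurrenceMap-class
#' @export
setMethod("occurrenceRaster", "OccurrenceMap", function(object) object@raster)

# ---- show methods ----

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "MovieStack [%s]: %d x %d px, %d frames (%.1f s @ %.1f fps), %.2f um/px\n",
    object@channelLabel, d[1], d[2], d[3],
    d[3] * object@frameIntervalS, 1 / object@frameIntervalS,
    object@pixelSizeUm))
})

setMethod("show", "DffStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "DffStack [%s]: %d x %d px, %d frames, dF/F0 range [%.3g, %.3g]\n",
    object@channelLabel, d[1], d[2], d[3],
    min(object@data), max(object@data)))
  cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "STMap", function(object) {
  cat(sprintf(
    "STMap (cell %d): %d positions x %d frames, extent %.1f um x %.1f s\n",
    object@cellId, nrow(object@matrix), ncol(object@matrix),
    diff(range(object@positionsUm)), ncol(object@matrix) * object@frameIntervalS))
})

setMethod("show", "OccurrenceMap", function(object) {
  cat(sprintf("OccurrenceMap: %d sites x %d frames, %d activations\n",
              nrow(object@raster), ncol(object@raster), sum(object@raster)))
})
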