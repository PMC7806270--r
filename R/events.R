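#' Segment calcium transient clusters (CTCs) from a PTCL series
#'
#' A CTC is one pacemaker wave seen at the network level: frames with a
#' particle count of at least \code{minCount} are active, and active runs
#' separated by quiet gaps shorter than \code{gapS} merge into one
#' cluster. When firing-site activations are supplied they are attached to
#' the cluster whose span contains them.
#'
#' @param ptclSeries a \code{"PtclSeries"} from \code{\link{summarizePtcls}}.
#' @param gapS merge gap, seconds.
#' @param minCount minimum particle count for an active frame.
#' @param firingSites optional \code{"FiringSites"} whose activations are
#'   assigned to clusters.
#' @return object of class \code{"CTCs"}: list with \code{ctcs}
#'   (data.frame: ctc_id, onset_s, end_s, duration_s, n_activations) and
#'   \code{activations} (data.frame: ctc_id, site_id, time_s).
#' @export
segmentCtcs <- function(ptclSeries, gapS = 1.0, minCount = 1,
                        firingSites = NULL) {
  stopifnot(inherits(ptclSeries, "PtclSeries"))
  dt <- ptclSeries$frameIntervalS
  active <- ptclSeries$count >= minCount
  runs <- activeRuns(active)
  if (nrow(runs) > 1) {
    merged <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      gap <- (runs$first[i] - last$last - 1) * dt
      if (gap < gapS) {
        last$last <- runs$last[i]
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, merged)
  }
  ctcs <- data.frame(ctc_id = seq_len(nrow(runs)),
                     onset_s = (runs$first - 1) * dt,
                     end_s = runs$last * dt)
  ctcs$duration_s <- ctcs$end_s - ctcs$onset_s
  act <- data.frame(ctc_id = integer(0), site_id = integer(0),
                    time_s = numeric(0))
  if (!is.null(firingSites) && nrow(firingSites$activations) > 0 &&
      nrow(ctcs) > 0) {
    a <- firingSites$activations
    ival <- findInterval(a$time_s, ctcs$onset_s)
    inside <- ival >= 1 & a$time_s <= ctcs$end_s[pmax(1, ival)]
    act <- data.frame(ctc_id = ival[inside], site_id = a$site_id[inside],
                      time_s = a$time_s[inside])
  }
  nAct <- tabulate(act$ctc_id, nbins = nrow(ctcs))
  ctcs$n_activations <- nAct
  structure(list(ctcs = ctcs, activations = act,
                 frameIntervalS = dt), class = "CTCs")
}

activeRuns <- function(active) {
  n <- length(active)
  if (!any(active)) return(data.frame(first = integer(0), last = integer(0)))
  d <- diff(c(FALSE, active))
  first <- which(d == 1)
  last <- which(diff(c(active, FALSE)) == -1)
  data.frame(first = first, last = last)
}

#' @export
print.CTCs <- function(x, ...) {
  cat(sprintf("CTCs: %d clusters, mean duration %.2f s, %d site activations\n",
              nrow(x$ctcs), mean(x$ctcs$duration_s), nrow(x$activations)))
  invisible(x)
}

#' Pacemaker frequency in cycles per minute
#'
#' @param ctcs a \code{"CTCs"} object (or an integer count).
#' @param durationS recording length, seconds.
#' @return 60 x count / durationS.
#' @export
frequencyCpm <- function(ctcs, durationS) {
  stopIfNot(durationS > 0, "durationS must be > 0")
  n <- if (inherits(ctcs, "CTCs")) nrow(ctcs$ctcs) else as.numeric(ctcs)
  60 * n / durationS
}

#' Estimate wave propagation velocity from onset times at known positions
#'
#' Least-squares fit of distance = v x onset + c over at least three
#' (distance, onset) pairs whose onsets were estimated with sub-frame
#' precision (half-maximum interpolation). The velocity is reported as
#' resolved only when the fit R-squared reaches \code{r2Min}; with all
#' onsets equal the wave is flagged unresolved (faster than the
#' field-of-view / frame-interval bound).
#'
#' @param onsetByPosition data.frame with columns \code{distance_um} and
#'   \code{onset_s}.
#' @param r2Min minimum R-squared to report a velocity.
#' @return object of class \code{"WaveKinematics"}: list with
#'   \code{velocity_mm_s}, \code{fit_r2}, \code{resolved}, \code{n}, and
#'   the input table.
#' @export
estimateVelocity <- function(onsetByPosition, r2Min = 0.5) {
  ob <- onsetByPosition
  stopIfNot(all(c("distance_um", "onset_s") %in% names(ob)),
            "need columns distance_um and onset_s")
  stopIfNot(nrow(ob) >= 3, "need >= 3 (distance, onset) pairs for a fit")
  if (stats::var(ob$onset_s) < 1e-18) {
    return(structure(list(velocity_mm_s = NA_real_, fit_r2 = NA_real_,
                          resolved = FALSE,
                          note = "unresolved (>= FOV/frame-interval bound)",
                          n = nrow(ob), onset_by_position = ob),
                     class = "WaveKinematics"))
  }
  fit <- stats::lm(distance_um ~ onset_s, data = ob)
  v <- unname(stats::coef(fit)[2]) / 1000  # um/s -> mm/s
  # noiseless inputs produce an exact fit; the perfect-fit warning from
  # summary.lm is a legitimate state here, not a problem
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(velocity_mm_s = if (r2 >= r2Min) v else NA_real_,
                 fit_r2 = r2, resolved = r2 >= r2Min && is.finite(v) && v > 0,
                 note = if (r2 >= r2Min) NULL else "low-R2 fit suppressed",
                 n = nrow(ob), onset_by_position = ob),
            class = "WaveKinematics")
}

#' @export
print.WaveKinematics <- function(x, ...) {
  if (x$resolved)
    cat(sprintf("WaveKinematics: %.1f mm/s (R2 = %.3f, n = %d)\n",
                x$velocity_mm_s, x$fit_r2, x$n))
  else cat(sprintf("WaveKinematics: %s (n = %d)\n",
                   if (is.null(x$note)) "unresolved" else x$note, x$n))
  invisible(x)
}

#' Measure per-wave propagation velocities across a network recording
#'
#' For each cell, a small ROI trace at the soma is extracted from the
#' dF/F0 stack and its transient onsets estimated by half-maximum
#' interpolation; onsets are grouped into waves using the network-mean
#' trace, and for each wave a distance-versus-onset regression (distance
#' from the earliest-firing cell) yields a velocity.
#'
#' @param dff a \code{\linkS4class{DffStack}}.
#' @param cellPositionsUm data.frame with columns x_um, y_um (e.g.
#'   \code{geometry$cells}).
#' @param roiHalfUm ROI half-width around each soma, micrometers.
#' @param matchWindowS maximum |cell onset - wave time| for assignment.
#' @param r2Min minimum R-squared per wave.
#' @return data.frame, one row per wave: wave_time_s, velocity_mm_s,
#'   fit_r2, n_cells, resolved.
#' @export
measureWaveVelocities <- function(dff, cellPositionsUm, roiHalfUm = 4,
                                  matchWindowS = 0.5, r2Min = 0.5) {
  stopifnot(is(dff, "DffStack"))
  nC <- nrow(cellPositionsUm)
  stopIfNot(nC >= 3, "need >= 3 cells")
  times <- frameTimes(dff)
  traces <- matrix(0, length(times), nC)
  px <- pixelSize(dff)
  fovW <- dim(dff@data)[2] * px; fovH <- dim(dff@data)[1] * px
  for (i in seq_len(nC)) {
    traces[, i] <- roiTrace(dff, c(
      max(0, cellPositionsUm$x_um[i] - roiHalfUm),
      min(fovW, cellPositionsUm$x_um[i] + roiHalfUm),
      max(0, cellPositionsUm$y_um[i] - roiHalfUm),
      min(fovH, cellPositionsUm$y_um[i] + roiHalfUm)))
  }
  global <- rowMeans(traces)
  waveT <- detectOnsets(global, frameInterval(dff))
  if (!length(waveT)) return(data.frame(wave_time_s = numeric(0),
                                        velocity_mm_s = numeric(0),
                                        fit_r2 = numeric(0),
                                        n_cells = integer(0),
                                        resolved = logical(0)))
  cellOnsets <- lapply(seq_len(nC), function(i)
    detectOnsets(traces[, i], frameInterval(dff)))
  out <- list()
  for (w in seq_along(waveT)) {
    on <- rep(NA_real_, nC)
    for (i in seq_len(nC)) {
      oi <- cellOnsets[[i]]
      if (!length(oi)) next
      j <- which.min(abs(oi - waveT[w]))
      if (abs(oi[j] - waveT[w]) <= matchWindowS) on[i] <- oi[j]
    }
    ok <- which(!is.na(on))
    if (length(ok) < 3) next
    origin <- ok[which.min(on[ok])]
    d <- sqrt((cellPositionsUm$x_um[ok] - cellPositionsUm$x_um[origin])^2 +
              (cellPositionsUm$y_um[ok] - cellPositionsUm$y_um[origin])^2)
    wk <- estimateVelocity(data.frame(distance_um = d, onset_s = on[ok]),
                           r2Min = r2Min)
    out[[length(out) + 1L]] <- data.frame(
      wave_time_s = waveT[w], velocity_mm_s = wk$velocity_mm_s,
      fit_r2 = wk$fit_r2, n_cells = length(ok), resolved = wk$resolved)
  }
  if (!length(out)) return(data.frame(wave_time_s = numeric(0),
                                      velocity_mm_s = numeric(0),
                                      fit_r2 = numeric(0),
                                      n_cells = integer(0),
                                      resolved = logical(0)))
  do.call(rbind, out)
}

#' Within-wave firing-site activation distribution
#'
#' For each CTC, site activation times are re-zeroed to the cluster onset
#' and histogrammed into \code{binMs} bins over a \code{horizonS} horizon
#' (default: twelve 85-ms bins over 1 s, the last truncated at 1 s),
#' converted to percentages of that cluster's activations, then averaged
#' across clusters. Activations beyond the horizon are excluded from the
#' bins (per-cluster percentages sum to at most 100).
#'
#' @param ctcs a \code{"CTCs"} object with attached activations.
#' @param binMs bin width, milliseconds.
#' @param horizonS histogram horizon, seconds.
#' @return data.frame: bin_start_ms, bin_end_ms, mean_pct, sem_pct,
#'   n_ctcs.
#' @export
firingDistribution <- function(ctcs, binMs = 85, horizonS = 1.0) {
  stopifnot(inherits(ctcs, "CTCs"))
  breaks <- unique(c(seq(0, horizonS, by = binMs / 1000), horizonS))
  if (max(breaks) < horizonS) breaks <- c(breaks, horizonS)
  nb <- length(breaks) - 1
  rows <- list()
  for (k in ctcs$ctcs$ctc_id) {
    a <- ctcs$activations[ctcs$activations$ctc_id == k, ]
    if (nrow(a) == 0) next
    rel <- a$time_s - ctcs$ctcs$onset_s[ctcs$ctcs$ctc_id == k]
    h <- graphics::hist(rel[rel >= 0 & rel < horizonS], breaks = breaks,
                        plot = FALSE, right = FALSE)$counts
    rows[[length(rows) + 1L]] <- 100 * h / nrow(a)
  }
  stopIfNot(length(rows) > 0, "no cluster has attached activations")
  Mx <- do.call(rbind, rows)
  data.frame(bin_start_ms = breaks[-length(breaks)] * 1000,
             bin_end_ms = breaks[-1] * 1000,
             mean_pct = colMeans(Mx),
             sem_pct = apply(Mx, 2, stats::sd) / sqrt(nrow(Mx)),
             n_ctcs = nrow(Mx))
}

#' Count firing-site activations in a window before each cluster
#'
#' Counts site activations within \code{[onset - windowS, onset)} of each
#' CTC (stochastic inter-cluster firing); the first cluster is skipped
#' when its window precedes the recording start.
#'
#' @param firingSites a \code{"FiringSites"} object.
#' @param ctcs a \code{"CTCs"} object.
#' @param windowS look-back window, seconds.
#' @return data.frame: ctc_id, onset_s, n_pre.
#' @export
preCtcEventCount <- function(firingSites, ctcs, windowS = 2.0) {
  stopifnot(inherits(firingSites, "FiringSites"), inherits(ctcs, "CTCs"))
  tt <- firingSites$activations$time_s
  out <- list()
  for (i in seq_len(nrow(ctcs$ctcs))) {
    on <- ctcs$ctcs$onset_s[i]
    if (on - windowS < 0) next
    out[[length(out) + 1L]] <- data.frame(
      ctc_id = ctcs$ctcs$ctc_id[i], onset_s = on,
      n_pre = sum(tt >= on - windowS & tt < on))
  }
  if (!length(out)) return(data.frame(ctc_id = integer(0),
                                      onset_s = numeric(0), n_pre = integer(0)))
  do.call(rbind, out)
}
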