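# shared fixtures and independent oracles

# brute-force breadth-first flood fill: the independent oracle for
# labelParticles / labelBinary
bfsLabel <- function(mat, connectivity = 8) {
  H <- nrow(mat); W <- ncol(mat)
  lab <- matrix(0L, H, W); cur <- 0L
  if (connectivity == 8) {
    di <- c(-1, -1, -1, 0, 0, 1, 1, 1); dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    di <- c(-1, 1, 0, 0); dj <- c(0, 0, -1, 1)
  }
  for (start in which(mat)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start; lab[start] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- (q - 1L) %% H + 1L; cc <- (q - 1L) %/% H + 1L
      for (k in seq_along(di)) {
        rr <- r + di[k]; c2 <- cc + dj[k]
        if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W &&
            mat[rr, c2] && lab[rr, c2] == 0L) {
          lab[rr, c2] <- cur
          queue <- c(queue, (c2 - 1L) * H + rr)
        }
      }
    }
  }
  lab
}

# canonical relabelling (by first occurrence, column-major) so two
# labelings can be compared independent of label order
canonLabels <- function(lab) {
  pos <- which(lab > 0L)  # column-major order
  if (!length(pos)) return(lab)
  ids <- lab[pos]
  lab[pos] <- match(ids, unique(ids))
  lab
}

# wrap a dF/F0 array into a DffStack directly (unit baseline, full mask)
makeDff <- function(arr, pixelSizeUm = 1, frameIntervalS = 1 / 33) {
  d <- dim(arr)
  new("DffStack", data = arr, f0Image = matrix(1, d[1], d[2]),
      mask = matrix(TRUE, d[1], d[2]), frameIntervalS = frameIntervalS,
      pixelSizeUm = pixelSizeUm, channelLabel = "test",
      f0Percentile = 0.10, provenance = "synthetic")
}

# small PtclSeries from a count vector
makeSeries <- function(count, frameIntervalS = 0.1) {
  structure(list(count = as.numeric(count),
                 area_um2 = as.numeric(count),
                 track_durations_s = numeric(0),
                 tracks = data.frame(),
                 frameIntervalS = frameIntervalS, pixelSizeUm = 1),
            class = "PtclSeries")
}

# default small network recording shared across files (memoised)
.fixtureEnv <- new.env(parent = emptyenv())
fixtureNetwork <- function() {
  if (is.null(.fixtureEnv$net)) {
    cfg <- generatorConfig(duration_s = 30, fov_width_um = 96,
                           fov_height_um = 96)
    rec <- generateNetworkMovie(cfg, seed = 42)
    pp <- preprocessMovie(rec$movie, register = FALSE)
    .fixtureEnv$net <- list(cfg = cfg, rec = rec, dff = pp$dff)
  }
  .fixtureEnv$net
}
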