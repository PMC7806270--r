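test_that("labelParticles agrees with hand-enumerated cases", {
  # all-false frame -> no particles
  lp <- labelParticles(matrix(FALSE, 5, 5))
  expect_equal(nrow(lp$particles), 0)

  # two disjoint 3x3 blocks in a 10x10 frame
  fr <- matrix(FALSE, 10, 10)
  fr[1:3, 1:3] <- TRUE; fr[7:9, 7:9] <- TRUE
  lp <- labelParticles(fr, pixelSizeUm = 0.5)
  expect_equal(nrow(lp$particles), 2)
  expect_equal(lp$particles$area_um2, c(9, 9) * 0.25)
  expect_equal(sort(lp$particles$area_px), c(9L, 9L))

  # diagonal touch: one particle under 8-connectivity, two under 4
  fr <- matrix(FALSE, 8, 8)
  fr[1:3, 1:3] <- TRUE; fr[4:6, 4:6] <- TRUE
  expect_equal(nrow(labelParticles(fr, connectivity = 8)$particles), 1)
  expect_equal(nrow(labelParticles(fr, connectivity = 4)$particles), 2)

  # min-area filter discards sub-threshold specks
  fr <- matrix(FALSE, 6, 6); fr[1, 1] <- TRUE; fr[4:5, 4:5] <- TRUE
  lp <- labelParticles(fr, minAreaPx = 4)
  expect_equal(nrow(lp$particles), 1)
  expect_equal(lp$particles$area_px, 4L)
})

test_that("flood fill matches brute-force BFS and EBImage on random frames", {
  set.seed(1234)
  nEB <- 0
  hasEB <- requireNamespace("EBImage", quietly = TRUE)
  for (i in 1:300) {
    fr <- matrix(runif(16 * 16) < runif(1, 0.2, 0.6), 16, 16)
    for (conn in c(8, 4)) {
      mine <- canonLabels(icWaves:::labelBinary(fr, conn))
      oracle <- canonLabels(bfsLabel(fr, conn))
      expect_identical(mine, oracle)
    }
    if (hasEB) {
      eb <- canonLabels(matrix(as.integer(EBImage::bwlabel(fr)), 16, 16))
      expect_identical(canonLabels(icWaves:::labelBinary(fr, 4)), eb)
      nEB <- nEB + 1
    }
  }
  expect_true(!hasEB || nEB == 300)
})

test_that("thresholding is specific, sensitive and monotone in k", {
  # zero-noise constant stack -> no active pixels
  z <- makeDff(array(0, dim = c(8, 8, 30)))
  expect_false(any(thresholdDff(z)))

  # synthetic event of amplitude 1.2 over noise sd 0.05 -> active at peak
  set.seed(7)
  arr <- array(rnorm(8 * 8 * 60, sd = 0.05), dim = c(8, 8, 60))
  arr <- sweep(arr, c(1, 2), apply(arr, c(1, 2), quantile, 0.1))  # re-zero like dff
  arr[4, 4, 30:33] <- arr[4, 4, 30:33] + 1.2
  dff <- makeDff(arr)
  act <- thresholdDff(dff, kSd = 3)
  expect_true(all(act[4, 4, 30:33]))

  # raising k never adds active pixels
  counts <- vapply(c(2, 3, 4, 5), function(k) sum(thresholdDff(dff, k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("track linkage and series summaries follow pixel overlap", {
  # single particle persisting 10 frames at 33 fps -> one track of 10/33 s
  bin <- array(FALSE, dim = c(8, 8, 15))
  bin[3:5, 3:5, 3:12] <- TRUE
  pmv <- particlesFromBinary(bin, frameIntervalS = 1 / 33, pixelSizeUm = 1)
  ps <- summarizePtcls(pmv)
  expect_equal(nrow(ps$tracks), 1)
  expect_equal(ps$track_durations_s, 10 / 33)
  expect_equal(ps$count[3:12], rep(1, 10))
  expect_equal(ps$area_um2[4], 9)

  # empty movie -> all-zero series
  ps0 <- summarizePtcls(particlesFromBinary(array(FALSE, dim = c(4, 4, 6)),
                                            1 / 33, 1))
  expect_true(all(ps0$count == 0) && all(ps0$area_um2 == 0))

  # two simultaneous non-overlapping blobs -> two tracks
  bin2 <- array(FALSE, dim = c(10, 10, 4))
  bin2[1:2, 1:2, ] <- TRUE; bin2[8:9, 8:9, ] <- TRUE
  ps2 <- summarizePtcls(particlesFromBinary(bin2, 1 / 33, 1, minAreaPx = 1))
  expect_equal(nrow(ps2$tracks), 2)
})

test_that("the 70-ms initiation rule reproduces its truth table", {
  dt <- 1 / 33
  mk <- function(frames, T = 10) {
    bin <- array(FALSE, dim = c(6, 6, T))
    for (f in frames) bin[2:3, 2:3, f] <- TRUE
    particlesFromBinary(bin, dt, 1, minAreaPx = 1)
  }
  # appears in frame 5, persists into frame 6 -> initiation
  ini <- detectInitiations(mk(c(5, 6)))
  expect_equal(ini$frame, 5L)
  # present in frames 4 and 5 at the same pixels -> frame 5 not an
  # initiation (frame 4 is: nothing before it, overlap after)
  ini <- detectInitiations(mk(c(4, 5)))
  expect_equal(ini$frame, 4L)
  # single-frame flash with no successor within 70 ms -> no initiation
  ini <- detectInitiations(mk(5))
  expect_equal(nrow(ini), 0)
  # successor 2 frames later (60.6 ms <= 70 ms) counts; 3 frames does not
  bin <- array(FALSE, dim = c(6, 6, 10))
  bin[2:3, 2:3, 5] <- TRUE; bin[2:3, 2:3, 7] <- TRUE
  expect_equal(detectInitiations(particlesFromBinary(bin, dt, 1, minAreaPx = 1))$frame,
               c(5L, 7L)[1])
  bin2 <- array(FALSE, dim = c(6, 6, 10))
  bin2[2:3, 2:3, 5] <- TRUE; bin2[2:3, 2:3, 8] <- TRUE
  expect_equal(nrow(detectInitiations(particlesFromBinary(bin2, dt, 1, minAreaPx = 1))),
               0)
})

test_that("shrinking the initiation window never adds initiations", {
  set.seed(42)
  for (rep in 1:20) {
    bin <- array(runif(8 * 8 * 20) < 0.2, dim = c(8, 8, 20))
    pmv <- particlesFromBinary(bin, 1 / 33, 1, minAreaPx = 1)
    wide <- detectInitiations(pmv, windowMs = 70)
    narrow <- detectInitiations(pmv, windowMs = 40)
    key <- function(d) paste(d$frame, d$centroid_x_um, d$centroid_y_um)
    expect_true(all(key(narrow) %in% key(wide)))
  }
})

test_that("site grouping and occurrence maps conserve every initiation", {
  ini <- data.frame(frame = c(1L, 5L, 9L, 12L),
                    time_s = c(0.1, 0.5, 0.9, 1.2),
                    centroid_x_um = c(10, 11, 30, 10.5),
                    centroid_y_um = c(10, 11, 30, 10),
                    area_um2 = 4)
  fs <- groupSites(ini, groupingRadiusUm = 5)
  expect_equal(nrow(fs$sites), 2)           # 2 um apart -> same site
  expect_equal(sum(fs$sites$n_activations), 4)

  fs2 <- groupSites(ini[c(1, 3), ], groupingRadiusUm = 5)
  expect_equal(nrow(fs2$sites), 2)          # 28 um apart -> two sites

  om <- buildOccurrenceMap(fs, nFramesT = 15, frameIntervalS = 1 / 33)
  expect_equal(sum(occurrenceRaster(om)), nrow(fs$activations))
  expect_equal(unname(rowSums(occurrenceRaster(om))[match(fs$sites$site_id, om@siteIds)]),
               fs$sites$n_activations)
  # lanes ordered by first activation
  firstFrames <- apply(occurrenceRaster(om), 1, function(r) which(r)[1])
  expect_true(!is.unsorted(firstFrames))

  # one site firing at frames {3, 30}
  one <- data.frame(frame = c(3L, 30L), time_s = c(3, 30) / 33,
                    centroid_x_um = 5, centroid_y_um = 5, area_um2 = 4)
  om1 <- buildOccurrenceMap(groupSites(one), nFramesT = 40,
                            frameIntervalS = 1 / 33)
  expect_equal(which(occurrenceRaster(om1)[1, ]), c(3L, 30L))

  # no sites -> empty but valid raster
  om0 <- buildOccurrenceMap(groupSites(ini[0, ]), 10, 1 / 33)
  expect_equal(dim(occurrenceRaster(om0)), c(0L, 10L))
})

test_that("recovered particle activity scales linearly with event rate", {
  # multipliers span the physiologically observed 8-22 cpm range; beyond
  # ~25 cpm the inter-wave quiescence vanishes and a percentile baseline
  # is no longer defined (see the methods vignette)
  base <- generatorConfig(duration_s = 20, fov_width_um = 96,
                          fov_height_um = 96)
  mult <- c(0.25, 0.5, 1, 1.4)
  meanCount <- vapply(mult, function(s) {
    cfg <- applyCondition(base, rate = s)
    rec <- generateNetworkMovie(cfg, seed = 9)
    pp <- preprocessMovie(rec$movie, register = FALSE)
    ps <- summarizePtcls(detectParticles(pp$dff))
    mean(ps$count)
  }, numeric(1))
  expect_true(all(diff(meanCount) > 0))
  expect_gt(cor(mult, meanCount), 0.95)
})
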