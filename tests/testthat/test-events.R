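test_that("cluster segmentation merges runs across sub-gap pauses", {
  dt <- 0.1
  count <- rep(0, 100)
  count[11:30] <- 2          # run 1: 1.0-3.0 s
  count[36:50] <- 1          # run 2: 3.5-5.0 s (gap 0.5 s)
  count[76:90] <- 3          # run 3: 7.5-9.0 s (gap 2.5 s)
  ps <- makeSeries(count, dt)
  ct <- segmentCtcs(ps, gapS = 1.0)
  expect_equal(nrow(ct$ctcs), 2)          # first two runs merge
  ct2 <- segmentCtcs(ps, gapS = 0.3)
  expect_equal(nrow(ct2$ctcs), 3)         # smaller gap keeps them apart
  expect_equal(ct$ctcs$onset_s[1], 1.0)
  expect_equal(ct$ctcs$end_s[1], 5.0)
  # minCount gates activity
  ct3 <- segmentCtcs(ps, gapS = 0.3, minCount = 2)
  expect_equal(nrow(ct3$ctcs), 2)
})

test_that("frequency is a pure count-per-time transform", {
  expect_equal(frequencyCpm(15L, 60), 15)
  expect_equal(frequencyCpm(0L, 60), 0)
  expect_error(frequencyCpm(3L, 0), "> 0")
})

test_that("velocity fitting is exact on noiseless lines and flags degeneracy", {
  ob <- data.frame(distance_um = c(0, 2000, 4000),
                   onset_s = c(0, 0.01, 0.02))
  wk <- estimateVelocity(ob)
  expect_true(wk$resolved)
  expect_equal(wk$velocity_mm_s, 200, tolerance = 1e-9)
  expect_equal(wk$fit_r2, 1)

  deg <- estimateVelocity(data.frame(distance_um = c(0, 100, 200),
                                     onset_s = c(0.5, 0.5, 0.5)))
  expect_false(deg$resolved)
  expect_match(deg$note, "unresolved")
  expect_error(estimateVelocity(data.frame(distance_um = 1, onset_s = 1)),
               ">= 3")
})

test_that("velocity estimates scale correctly with the generated velocity", {
  vFit <- vapply(c(110, 220), function(v) {
    cfg <- generatorConfig(fov_width_um = 1300, fov_height_um = 100,
                           pixel_size_um = 4, duration_s = 12,
                           noise_sd_dff = 0.01, wave_velocity_mm_s = v)
    rec <- generateNetworkMovie(cfg, seed = 21)
    pp <- suppressWarnings(preprocessMovie(rec$movie, register = FALSE))
    wv <- measureWaveVelocities(pp$dff, rec$geometry$cells)
    mean(wv$velocity_mm_s[wv$resolved])
  }, numeric(1))
  expect_equal(vFit[2] / vFit[1], 2, tolerance = 0.25)
})

test_that("within-wave firing distribution is binned as configured", {
  mkCtc <- function(times, onset = 0, end = 3) {
    structure(list(
      ctcs = data.frame(ctc_id = 1L, onset_s = onset, end_s = end,
                        duration_s = end - onset,
                        n_activations = length(times)),
      activations = data.frame(ctc_id = 1L, site_id = 1L, time_s = times),
      frameIntervalS = 1 / 33), class = "CTCs")
  }
  # all activations at onset -> 100% in bin 1
  fd <- firingDistribution(mkCtc(rep(0, 10)))
  expect_equal(fd$mean_pct[1], 100)
  expect_equal(sum(fd$mean_pct[-1]), 0)
  expect_equal(nrow(fd), 12)                    # 11 x 85 ms + truncated 12th
  expect_equal(fd$bin_end_ms[12], 1000)

  # uniform activations over 1 s -> pct proportional to bin width
  u <- seq(0, 0.9999, length.out = 2000)
  fdU <- firingDistribution(mkCtc(u))
  expect_equal(fdU$mean_pct[1:11], rep(8.5, 11), tolerance = 0.01)
  expect_equal(fdU$mean_pct[12], 6.5, tolerance = 0.02)
  expect_lte(sum(fdU$mean_pct), 100 + 1e-9)

  # activations beyond the horizon are excluded from the bins
  fdX <- firingDistribution(mkCtc(c(0, 0.5, 2.5)))
  expect_equal(sum(fdX$mean_pct), 200 / 3, tolerance = 1e-9)
})

test_that("pre-cluster activation counts respect the look-back window", {
  fs <- structure(list(
    sites = data.frame(site_id = 1L, x_um = 0, y_um = 0,
                       n_activations = 5L, first_time_s = 0.5),
    activations = data.frame(site_id = 1L, frame = 1:5,
                             time_s = c(0.5, 3.0, 3.5, 3.9, 10),
                             x_um = 0, y_um = 0)), class = "FiringSites")
  ct <- structure(list(
    ctcs = data.frame(ctc_id = 1:2, onset_s = c(1, 4), end_s = c(2, 6),
                      duration_s = c(1, 2), n_activations = c(0L, 0L)),
    activations = data.frame(ctc_id = integer(0), site_id = integer(0),
                             time_s = numeric(0)),
    frameIntervalS = 1 / 33), class = "CTCs")
  pre <- preCtcEventCount(fs, ct, windowS = 2)
  # first CTC skipped (window would precede t = 0 ... no: onset 1 - 2 < 0)
  expect_equal(pre$ctc_id, 2L)
  expect_equal(pre$n_pre, 3L)   # 3.0, 3.5, 3.9 within [2, 4)
  # no inter-cluster activations -> zero
  fs0 <- fs; fs0$activations <- fs$activations[0, ]
  expect_equal(preCtcEventCount(fs0, ct, windowS = 2)$n_pre, 0L)
})

test_that("wave frequency and peak intervals are mutually consistent", {
  fx <- fixtureNetwork()
  ps <- summarizePtcls(detectParticles(fx$dff))
  ct <- segmentCtcs(ps)
  freq <- frequencyCpm(ct, fx$cfg$duration_s)
  ids <- fx$rec$geometry$cells$cell_id
  iv <- unlist(lapply(ids, function(cid) {
    sm <- buildSTMap(fx$dff, cellAxis(fx$rec$geometry, cid),
                     widthUm = 10, cellId = cid)
    peakIntervals(sm)
  }))
  expect_gt(length(iv), 3)
  expect_equal(freq * mean(iv), 60, tolerance = 0.1)
})

test_that("cluster duration shrinks as within-wave firing is truncated", {
  # ryanodine-like behaviour: blocking late within-wave firing shortens
  # the measured cluster, emulated by shrinking the firing decay tau
  meanDur <- vapply(c(0.6, 0.15, 0.04), function(tau) {
    cfg <- generatorConfig(fov_width_um = 150, fov_height_um = 40,
                           duration_s = 20, cell_length_um = 130,
                           within_wave_decay_tau_s = tau)
    rec <- generateSingleCellMovie(cfg, seed = 33)
    pp <- preprocessMovie(rec$movie, register = FALSE)
    ct <- segmentCtcs(summarizePtcls(detectParticles(pp$dff)))
    mean(ct$ctcs$duration_s)
  }, numeric(1))
  expect_true(all(diff(meanDur) < 0))
})

test_that("stochastic pre-cluster firing rises when clusters are suppressed", {
  # suppressed-pacemaker condition: sparse clusters plus brief stochastic
  # wave-independent sparks in between, versus a spark-free control
  runOne <- function(bgHz, sd) {
    cfg <- generatorConfig(fov_width_um = 150, fov_height_um = 40,
                           duration_s = 30, cell_length_um = 130,
                           background_firing_hz = bgHz, wave_rate_cpm = 6,
                           site_event_duration_s = 0.2)
    rec <- generateSingleCellMovie(cfg, seed = sd)
    pp <- preprocessMovie(rec$movie, register = FALSE)
    pmv <- detectParticles(pp$dff)
    fs <- groupSites(detectInitiations(pmv))
    ct <- segmentCtcs(summarizePtcls(pmv), firingSites = fs)
    preCtcEventCount(fs, ct, windowS = 2)$n_pre
  }
  pre <- unlist(lapply(12:14, function(sd) runOne(0.1, sd)))
  ctl <- unlist(lapply(12:14, function(sd) runOne(0, sd)))
  expect_gt(mean(pre), mean(ctl))
  expect_equal(mean(ctl), 0)
})
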