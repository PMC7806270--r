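test_that("generator config validates its invariants", {
  cfg <- generatorConfig()
  expect_s3_class(cfg, "GeneratorConfig")
  expect_error(generatorConfig(frame_rate_fps = 300), "frame_rate_fps")
  expect_error(generatorConfig(event_duration_s = -1), "positive")
  expect_error(generatorConfig(sites_per_cell_range = c(0, 12)), "range")
  expect_error(generatorConfig(nonsense_field = 1), "unknown")
})

test_that("network geometry matches the configured point process", {
  cfg <- generatorConfig(cell_density_per_mm2 = 0)
  geom <- generateNetworkGeometry(cfg, seed = 1)
  expect_equal(nrow(geom$cells), 0)

  # Poisson mean: density x area, checked over seeds (no hard core so the
  # expectation is exact)
  cfg <- generatorConfig(fov_width_um = 500, fov_height_um = 500,
                         cell_density_per_mm2 = 300, min_separation_um = 0)
  n <- vapply(1:30, function(s)
    nrow(generateNetworkGeometry(cfg, seed = s)$cells), numeric(1))
  expect_lt(abs(mean(n) - 75), 3 * sqrt(75 / 30))

  # hard-core separation respected
  cfg <- generatorConfig()
  geom <- generateNetworkGeometry(cfg, seed = 7)
  if (nrow(geom$cells) >= 2)
    expect_gte(min(dist(geom$cells[, c("x_um", "y_um")])),
               cfg$min_separation_um)

  # site counts never exceed the truncation range (border-clipped cells
  # may hold fewer sites than drawn)
  expect_true(all(geom$cells$n_sites <= 12))
  expect_gt(sum(geom$cells$n_sites), 0)
  expect_error(generateNetworkGeometry(generatorConfig(
    fov_width_um = 4, fov_height_um = 4)), "too small")
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- generatorConfig(duration_s = 5, fov_width_um = 64,
                         fov_height_um = 64, cell_density_per_mm2 = 2000,
                         cell_length_um = 50)
  a <- generateNetworkMovie(cfg, seed = 11)
  b <- generateNetworkMovie(cfg, seed = 11)
  expect_identical(a$movie@data, b$movie@data)
  expect_identical(a$schedule, b$schedule)
  expect_identical(a$geometry$cells, b$geometry$cells)
})

test_that("wave scheduling reproduces the configured rate and kinematics", {
  # zero jitter, 60 s at 14.9 cpm -> 14 or 15 onsets
  cfg <- generatorConfig(wave_jitter_s = 0)
  geom <- generateNetworkGeometry(cfg, seed = 2)
  sch <- scheduleCtcs(cfg, geom, seed = 5)
  expect_true(length(unique(sch$wave_id)) %in% c(14L, 15L))

  # rate conservation: empirical mean wave count over seeds within 3 SE
  cfg <- generatorConfig()
  counts <- vapply(1:25, function(s)
    length(unique(scheduleCtcs(cfg, geom, seed = s)$wave_id)), numeric(1))
  expect_lt(abs(mean(counts) - 14.9), 3 * sd(counts) / sqrt(25))

  # two cells 1 mm apart at 219 mm/s -> onset difference 1/219 s
  g2 <- structure(list(
    cells = data.frame(cell_id = 1:2, x_um = c(50, 1050), y_um = 25,
                       theta = 0, axis_t_min = -40, axis_t_max = 40,
                       n_sites = 5L),
    sites = data.frame(cell_id = integer(0), site_id = integer(0),
                       x_um = numeric(0), y_um = numeric(0)),
    fov_um = c(width = 1100, height = 50)), class = "CellGeometry")
  cfgV <- generatorConfig(fov_width_um = 1100, fov_height_um = 50,
                          duration_s = 10, wave_jitter_s = 0)
  schV <- scheduleCtcs(cfgV, g2, seed = 3)
  d <- vapply(split(schV$onset_s, schV$wave_id),
              function(x) abs(diff(x)), numeric(1))
  expect_equal(unname(d), rep(1000 / 219000, length(d)), tolerance = 1e-9)

  # decay tau -> 0: all site firings at the cell's wave onset
  cfg0 <- generatorConfig(within_wave_decay_tau_s = 0, fov_width_um = 150,
                          fov_height_um = 40, duration_s = 10,
                          cell_length_um = 130)
  rec0 <- generateSingleCellMovie(cfg0, seed = 4)
  byWave <- split(rec0$schedule$onset_s, rec0$schedule$wave_id)
  expect_true(all(vapply(byWave, function(x) diff(range(x)) == 0, logical(1))))
})

test_that("within-wave firing mass is front-loaded into the first ~256 ms", {
  cfg <- generatorConfig(fov_width_um = 150, fov_height_um = 40,
                         duration_s = 30, cell_length_um = 130)
  frac <- vapply(1:5, function(s) {
    rec <- generateSingleCellMovie(cfg, seed = s)
    sch <- rec$schedule
    rel <- unlist(lapply(split(sch$onset_s, sch$wave_id),
                         function(x) x - min(x)))
    mean(rel < 3 * 0.085)
  }, numeric(1))
  expect_true(all(frac >= 0.5))
})

test_that("rendered single events reproduce amplitude and duration", {
  cfg <- generatorConfig(fov_width_um = 80, fov_height_um = 40,
                         duration_s = 6, noise_sd_dff = 0,
                         cell_length_um = 60)
  geom <- structure(list(
    cells = data.frame(cell_id = 1L, x_um = 40, y_um = 20, theta = 0,
                       axis_t_min = -30, axis_t_max = 30, n_sites = 1L),
    sites = data.frame(cell_id = 1L, site_id = 1L, x_um = 40, y_um = 20),
    fov_um = c(width = 80, height = 40)), class = "CellGeometry")
  sch <- data.frame(wave_id = 1L, cell_id = 1L, site_id = 0L, onset_s = 1,
                    duration_s = 2.1, amplitude_dff = 1.2, spread_um = 30,
                    x_um = 40, y_um = 20, channel = "ICC")
  class(sch) <- c("GroundTruthSchedule", "data.frame")
  mov <- renderMovie(geom, sch, cfg)
  # peak dF/F0 at the centroid equals the amplitude within 1% (sampling)
  ctr <- mov@data[20, 40, ]
  f0 <- cfg$background_offset + cfg$baseline_f0
  dffCtr <- (ctr - f0) / cfg$baseline_f0
  expect_equal(max(dffCtr), 1.2, tolerance = 0.01)

  # FWHM of the centroid trace reproduces the configured duration within
  # one frame interval; oracle: dense brute-force evaluation of the kernel
  tFine <- seq(0, 5, by = 1e-4)
  kFine <- icWaves:::transientKernel(tFine, 2.1, cfg$indicator_rise_s,
                                     cfg$indicator_decay_s)
  oracleFwhm <- diff(range(tFine[kFine >= 0.5]))
  expect_equal(oracleFwhm, 2.1, tolerance = 1e-3)
  half <- max(dffCtr) / 2
  measured <- sum(dffCtr >= half) * mov@frameIntervalS
  expect_lt(abs(measured - 2.1), mov@frameIntervalS + 1e-9)

  # empty schedule, zero noise -> constant baseline, every pixel static
  mov0 <- renderMovie(geom, sch[0, ], cfg)
  expect_equal(max(mov0@data) - min(mov0@data),
               cfg$baseline_f0)  # footprint vs background, static in time
  expect_true(all(apply(mov0@data, c(1, 2), function(x) diff(range(x))) == 0))

  # schedule row outside the FOV names the offending row
  bad <- sch; bad$x_um <- 500
  expect_error(renderMovie(geom, bad, cfg), "row 1")
})

test_that("condition scaling behaves as multipliers on the config", {
  cfg <- generatorConfig()
  expect_equal(applyCondition(cfg, rate = 1, amplitude = 1, duration = 1),
               cfg)
  nic <- applyCondition(cfg, rate = 0.105)
  expect_equal(nic$wave_rate_cpm, 14.9 * 0.105)
  off <- applyCondition(cfg, rate = 0)
  geom <- generateNetworkGeometry(cfg, seed = 3)
  expect_equal(nrow(scheduleCtcs(off, geom, seed = 3)), 0)
  expect_error(applyCondition(cfg, rate = -1), ">= 0")
})

test_that("dual-channel ground truth obeys the configured lags exactly", {
  cfg <- generatorConfig(duration_s = 12, fov_width_um = 80,
                         fov_height_um = 80)
  dc <- generateDualChannel(cfg, seed = 2)
  icc <- dc$schedule[dc$schedule$channel == "ICC", ]
  smc <- dc$schedule[dc$schedule$channel == "SMC", ]
  m <- merge(icc, smc, by = c("wave_id", "cell_id"))
  expect_true(nrow(m) > 0)
  expect_equal(m$onset_s.y - m$onset_s.x,
               rep(cfg$icc_smc_latency_ms / 1000, nrow(m)))
  # latency additivity of the ground truth: ICC->disp = ICC->SMC + SMC->disp
  expect_equal(cfg$icc_smc_latency_ms + cfg$smc_disp_latency_ms, 176)
  # zero-latency config collapses the channels
  cfg0 <- generatorConfig(duration_s = 8, fov_width_um = 80,
                          fov_height_um = 80, icc_smc_latency_ms = 0)
  dc0 <- generateDualChannel(cfg0, seed = 2)
  icc0 <- dc0$schedule[dc0$schedule$channel == "ICC", ]
  smc0 <- dc0$schedule[dc0$schedule$channel == "SMC", ]
  expect_equal(sort(icc0$onset_s), sort(smc0$onset_s))
})
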