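staticMovie <- function(seed = 1, noise = 0.02) {
  cfg <- generatorConfig(duration_s = 3, fov_width_um = 64,
                         fov_height_um = 64, noise_sd_dff = noise,
                         wave_rate_cpm = 0, cell_length_um = 50)
  # deterministic two-cell geometry so registration has image structure
  geom <- structure(list(
    cells = data.frame(cell_id = 1:2, x_um = c(22, 45), y_um = c(20, 44),
                       theta = c(0.4, 2.0), axis_t_min = -22,
                       axis_t_max = 22, n_sites = 5L),
    sites = data.frame(cell_id = integer(0), site_id = integer(0),
                       x_um = numeric(0), y_um = numeric(0)),
    fov_um = c(width = 64, height = 64)), class = "CellGeometry")
  sch <- data.frame(wave_id = integer(0), cell_id = integer(0),
                    site_id = integer(0), onset_s = numeric(0),
                    duration_s = numeric(0), amplitude_dff = numeric(0),
                    spread_um = numeric(0), x_um = numeric(0),
                    y_um = numeric(0), channel = character(0))
  class(sch) <- c("GroundTruthSchedule", "data.frame")
  list(cfg = cfg, geom = geom,
       movie = renderMovie(geom, sch, cfg, seed = seed + 1))
}

test_that("registration recovers an injected rigid shift", {
  sm <- staticMovie()
  d <- sm$movie@data
  T <- dim(d)[3]
  # stationary movie: all shifts ~0
  reg0 <- registerTranslation(sm$movie)
  expect_lt(max(abs(reg0$driftUm$dx_um)), 0.3)
  expect_lt(max(abs(reg0$driftUm$dy_um)), 0.3)

  # inject +3 px x-shift from frame 50 onward
  shifted <- d
  for (t in 50:T) {
    fr <- matrix(median(d[, , t]), dim(d)[1], dim(d)[2])
    fr[, 4:dim(d)[2]] <- d[, 1:(dim(d)[2] - 3), t]
    shifted[, , t] <- fr
  }
  movS <- new("MovieStack", data = shifted,
              frameIntervalS = sm$movie@frameIntervalS,
              pixelSizeUm = sm$movie@pixelSizeUm, channelLabel = "ICC")
  reg <- registerTranslation(movS)
  jump <- mean(reg$driftUm$dx_um[50:T]) - mean(reg$driftUm$dx_um[1:49])
  expect_equal(jump, 3 * sm$movie@pixelSizeUm, tolerance = 0.15)

  # idempotence: re-registering the stabilised output gives shifts <= 0.25 px
  reg2 <- registerTranslation(reg$movie)
  expect_lt(max(abs(reg2$driftUm$dx_um)) / sm$movie@pixelSizeUm, 0.25)
  expect_lt(max(abs(reg2$driftUm$dy_um)) / sm$movie@pixelSizeUm, 0.25)

  # all-constant movie: zero shifts, no error
  cm <- new("MovieStack", data = array(5, dim = c(8, 8, 4)),
            frameIntervalS = 0.03, pixelSizeUm = 1, channelLabel = "x")
  regc <- registerTranslation(cm)
  expect_true(all(regc$driftUm$dx_um == 0) && all(regc$driftUm$dy_um == 0))
})

test_that("background subtraction recovers the additive offset", {
  # uniform movie of value b -> all zeros
  u <- new("MovieStack", data = array(7, dim = c(10, 10, 5)),
           frameIntervalS = 0.03, pixelSizeUm = 1, channelLabel = "x")
  expect_true(all(movieData(subtractBackground(u)) == 0))

  # uniform b plus one bright blob -> blob reduced by b
  d <- array(3, dim = c(10, 10, 5)); d[5, 5, ] <- 13
  m <- new("MovieStack", data = d, frameIntervalS = 0.03, pixelSizeUm = 1,
           channelLabel = "x")
  out <- movieData(subtractBackground(m))
  expect_equal(out[5, 5, 1], 10)
  expect_equal(out[1, 1, 1], 0)

  # synthetic movie with known offset: recovered within the noise SD
  sm <- staticMovie(noise = 0.02)
  est <- estimateBackground(sm$movie)
  expect_lt(abs(est - sm$cfg$background_offset),
            sm$cfg$noise_sd_dff * sm$cfg$baseline_f0)
})

test_that("Gaussian smoothing kernel matches direct computation and conserves mass", {
  K <- smoothingKernel(pixelSizeUm = 0.5, windowUm = 1.5, sigmaPx = 1.0)
  g <- dnorm(-1:1, sd = 1)
  KO <- outer(g, g) / sum(outer(g, g))
  expect_equal(K, KO, tolerance = 1e-12)
  expect_equal(sum(K), 1)

  # constant frame is a fixed point (border renormalisation included)
  m <- new("MovieStack", data = array(4, dim = c(12, 12, 2)),
           frameIntervalS = 0.03, pixelSizeUm = 0.5, channelLabel = "x")
  expect_equal(movieData(gaussianSmooth(m)), movieData(m), tolerance = 1e-12)

  # unit interior impulse: response equals the kernel; total mass preserved
  d <- array(0, dim = c(12, 12, 1)); d[6, 6, 1] <- 1
  mi <- new("MovieStack", data = d, frameIntervalS = 0.03, pixelSizeUm = 0.5,
            channelLabel = "x")
  out <- movieData(gaussianSmooth(mi))[, , 1]
  expect_equal(out[5:7, 5:7], KO, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)

  # sub-pixel window: identity with a warning
  tiny <- new("MovieStack", data = array(1, dim = c(4, 4, 1)),
              frameIntervalS = 1, pixelSizeUm = 2, channelLabel = "x")
  expect_warning(gaussianSmooth(tiny), "window")
})

test_that("dF/F0 normalisation is exact, scale-invariant and guarded", {
  # constant movie -> dff identically 0
  cm <- new("MovieStack", data = array(2, dim = c(6, 6, 20)),
            frameIntervalS = 0.03, pixelSizeUm = 1, channelLabel = "x")
  expect_true(all(movieData(computeDff(cm)) == 0))

  # baseline 1.0 with a transient peaking at 2.2 -> peak dF/F0 = 1.2
  d <- array(1, dim = c(4, 4, 40)); d[2, 2, 20:23] <- 2.2
  m <- new("MovieStack", data = d, frameIntervalS = 0.03, pixelSizeUm = 1,
           channelLabel = "x")
  dff <- computeDff(m)
  expect_equal(max(movieData(dff)), 1.2, tolerance = 1e-12)
  expect_equal(f0Image(dff)[2, 2], 1)

  # scale invariance: c * movie gives identical dF/F0
  m3 <- new("MovieStack", data = 3.7 * d, frameIntervalS = 0.03,
            pixelSizeUm = 1, channelLabel = "x")
  expect_equal(movieData(computeDff(m3)), movieData(dff), tolerance = 1e-12)

  # all-zero movie -> explicit error
  z <- new("MovieStack", data = array(0, dim = c(4, 4, 5)),
           frameIntervalS = 0.03, pixelSizeUm = 1, channelLabel = "x")
  expect_error(computeDff(z), "no baseline signal")

  # generator oracle: zero-noise movie recovers the flat baseline exactly
  cfg <- generatorConfig(duration_s = 4, fov_width_um = 64,
                         fov_height_um = 64, noise_sd_dff = 0)
  rec <- generateNetworkMovie(cfg, seed = 8)
  dff2 <- computeDff(rec$movie)
  fp <- footprintMask(rec$geometry, cfg)
  expect_true(all(abs(f0Image(dff2)[fp] -
                      (cfg$baseline_f0 + cfg$background_offset)) < 1e-9))
})
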