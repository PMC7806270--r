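# icWaves

Particle-based analysis of pacemaker calcium waves in interstitial cell
of Cajal (ICC) networks.

Submucosal ICC (ICC-SM) of the proximal colon fire rhythmic calcium
waves (~15 cycles/min) that pace smooth muscle. Each wave is a cluster
of calcium transients (CTC): at network scale a ~2 s, ~1.2 ΔF/F₀,
~37 µm whole-cell transient propagating at hundreds of mm/s; at
subcellular scale a volley from 5–12 firing sites per cell,
concentrated in the first ~256 ms of the wave. icWaves implements the
measurement chain for such time-lapse fluorescence recordings, for
researchers quantifying pacemaker activity and its pharmacology:

- motion stabilisation, background subtraction, smoothing, and
  per-pixel ΔF/F₀ = (F − F₀)/F₀ with a percentile baseline;
- **PTCL detection**: flood-fill labelling of supra-threshold pixels per
  frame, with per-frame summed area/count and pixel-overlap track
  durations;
- **firing/initiation sites**: a particle that overlaps nothing in the
  previous frame but overlaps a particle within the following 70 ms is
  an initiation; initiations are grouped into sites (5 µm radius) and
  displayed as site × time occurrence maps;
- **spatiotemporal maps (STMaps)** along a cell axis, with per-event
  duration, amplitude and spatial spread measured at half-maximum, map
  overlap percentages, and peak-to-peak intervals;
- **wave metrics**: CTC segmentation (1 s merge gap), frequency in
  cycles/min, propagation velocity from the regression
  distance = v·onset + c over sub-frame-interpolated half-maximum
  onsets, within-wave firing distributions in 85-ms bins, and
  pre-cluster event counts;
- **dual-channel latencies** between pixel-matched ICC and SMC channels
  and a displacement trace;
- **network geometry** (soma density, mean nearest-neighbour
  separation) and **condition statistics** (% of control, Welch t-test,
  one-way ANOVA + Tukey HSD).

Because such recordings are rarely shareable, the package includes a
seeded synthetic-movie generator calibrated to the reference biology
(14.9 cpm, 2.1 s, 1.2 ΔF/F₀, 36.8 µm, 219 mm/s, 8.2 sites/cell,
56/120 ms latencies, 312 somata/mm², 33 fps) that emits a ground-truth
event schedule, so every stage is validated by parameter recovery. See
the methods vignette (`vignettes/icc-pacemaker-analysis.Rmd`) for the
model, parameter meanings and numerical choices.

## Worked example

```r
library(icWaves)

cfg <- generatorConfig(duration_s = 30)       # reference-calibrated defaults
rec <- generateNetworkMovie(cfg, seed = 1)    # movie + ground truth
rec$movie
#> MovieStack [ICC]: 128 x 128 px, 990 frames (30.0 s @ 33.0 fps), 1.00 um/px

pp     <- preprocessMovie(rec$movie)          # register, subtract, smooth, dF/F0
series <- summarizePtcls(detectParticles(pp$dff))
series
#> PtclSeries: 990 frames; mean area 1592.59 um2/frame, mean count 2.67/frame, 97 tracks

ctcs <- segmentCtcs(series)
frequencyCpm(ctcs, cfg$duration_s)
#> wave frequency: 14.0 cpm

ids <- selectAnalysisCells(rec$geometry, cfg) # fully visible, non-crossing cells
ev  <- do.call(rbind, lapply(ids, function(cid)
  segmentEvents(buildSTMap(pp$dff, cellAxis(rec$geometry, cid),
                           widthUm = 10, cellId = cid))))
head(ev[, c("cell_id", "onset_s", "duration_s", "amplitude_dff", "spread_um")], 4)
#>   cell_id onset_s duration_s amplitude_dff spread_um
#> 1       1    2.36       2.39          1.20        38
#> 2       1    6.36       2.12          1.19        38
#> 3       1   10.33       2.03          1.16        42
#> 4       1   14.42       2.00          1.14        34
```

Over this recording's 21 analysable events the mean duration is 2.19 s,
the mean amplitude 1.19 ΔF/F₀ and the mean spread 37.2 µm — the
generator was configured at 2.1 s / 1.2 / 36.8 µm, so the pipeline
recovers its inputs. The wave count (14 cpm here over 30 s) fluctuates
a little below the configured 14.9 because occasional tight wave pairs
merge under the 1-s cluster gap.

Single-cell (high-magnification) recordings exercise the firing-site
chain:

```r
sc <- generateSingleCellMovie(generatorConfig(
  fov_width_um = 150, fov_height_um = 40, duration_s = 30,
  cell_length_um = 130), seed = 5)
fs <- groupSites(detectInitiations(detectParticles(
  preprocessMovie(sc$movie, register = FALSE)$dff)))
fs
#> FiringSites: 7 sites, 58 activations
sc$nSitesPlanted
#> [1] 7
```

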