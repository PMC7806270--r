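---
title: "Particle-based analysis of pacemaker calcium waves in ICC networks"
author: "icWaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-based analysis of pacemaker calcium waves in ICC networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological system and the measurement problem

Interstitial cells of Cajal along the submucosal surface of the colonic
circular muscle (ICC-SM) form an electrically coupled network that paces
gut motility. Imaged with a genetically encoded calcium indicator
(GCaMP6f-class), the network fires rhythmic calcium waves — at low
magnification roughly 15 cycles/min, each a ~2 s whole-cell transient of
~1.2 dF/F0 peak and ~37 um spatial spread that propagates across the
network at a few hundred mm/s. At high magnification each cell resolves
into 5–12 subcellular firing sites whose brief transients cluster at the
start of every wave (a calcium transient cluster, CTC). In dual-sensor
preparations the ICC wave precedes calcium in smooth muscle cells (SMC)
by tens of milliseconds, and tissue displacement follows SMCs by a
further ~0.1 s.

icWaves reimplements the full measurement chain for such recordings —
and, because raw recordings of this kind are rarely shareable, pairs it
with a seeded forward model (the synthetic generator) whose ground-truth
schedule makes every stage verifiable by parameter recovery.

## The analysis chain

1. **Preprocessing** (`preprocessMovie`): rigid translation registration
   against the temporal-mean image (FFT cross-correlation, parabolic
   subpixel refinement; frames are shifted back by the rounded offset,
   edge fill = frame median), scalar background subtraction (mean of the
   darkest 1% of the temporal-mean image — the indicator-free haze),
   per-frame Gaussian smoothing (1.5 x 1.5 um window, SD 1 px), and
   pixelwise dF/F0 with F0 = the 10th temporal percentile per pixel.
2. **Particles** (`detectParticles`): a pixel-frame is active when its
   dF/F0 exceeds the pixel's baseline mean + `kSd` noise SDs; active
   pixels are flood-filled per frame into PTCLs (run-based union-find,
   8-connectivity, minimum 4 px). Per-frame summed PTCL area and count,
   and track durations via frame-to-frame pixel-overlap linkage
   (`summarizePtcls`).
3. **Firing sites** (`detectInitiations`, `groupSites`): a particle is an
   initiation iff it overlaps nothing in the previous frame but overlaps
   some particle within the following 70 ms; initiations are grouped
   into sites by greedy running-mean centroid clustering (5 um radius)
   and displayed as a site x time occurrence map.
4. **STMaps** (`buildSTMap`, `segmentEvents`): fluorescence averaged
   across the cell diameter along an axis polyline, position x time;
   supra-threshold regions (half of the map's robust maximum) become
   events whose duration/spread are the temporal/spatial extents at half
   of the event's own peak.
5. **Waves** (`segmentCtcs`, `estimateVelocity`, `firingDistribution`):
   active runs of the PTCL count series merged across gaps < 1 s form
   CTCs; distance-versus-onset regression over cells (onsets at
   half-maximum, sub-frame interpolated) gives the propagation velocity;
   site activations re-zeroed to cluster onset and histogrammed in 85-ms
   bins over 1 s give the within-wave firing distribution.
6. **Dual channel** (`roiTrace`, `detectOnsets`, `measureLatencies`):
   pixel-matched ROI traces, per-event half-maximum onsets, greedy
   nearest matching into ICC/SMC/displacement triplets, latencies in ms.
7. **Geometry** (`detectCellBodies`, `cellDensity`,
   `meanMinSeparation`): soma density and mean nearest-neighbour
   separation from still images.
8. **Condition statistics** (`normalizeToControl`, `compareTwo`,
   `compareMany`): percent-of-control normalisation, Welch t-test, and
   one-way ANOVA with Tukey HSD, with the conventional star tiers
   (p < 0.05/0.01/0.001/0.0001).

## What the generator emulates

`generatorConfig()` defaults are calibrated to the reference biology:
14.9 waves/min (period jitter SD 0.15 s, ~4% CV — pacemaker rhythms are
clock-like), velocity 219 mm/s with a random origin cell per wave and
radial propagation, whole-cell transients of 2.1 s FWHM duration
(drawn once per wave, 0.05 s per-cell scatter — the plateau is a
property of the shared slow-wave event, not of individual cells),
1.2 dF/F0 amplitude and 36.8 um FWHM spread, 312 somata/mm^2 with a
40-um hard-core (the reference network is regular: its mean
nearest-neighbour separation, 49.3 um, far exceeds the ~28 um a Poisson
process would give at that density), 5–12 firing sites per cell
(discretised normal, mean 8.2, SD 2), ICC-to-SMC latency 56 ms,
SMC-to-displacement 120 ms, and 33 fps sampling.

Two imaging regimes mirror the two magnifications at which the
measurements are made. *Network mode* (`generateNetworkMovie`) renders
one whole-cell transient per cell per wave — this feeds wave frequency,
STMap metrics and velocity. *Single-cell mode*
(`generateSingleCellMovie`) renders subcellular site-level transients
(3.5 um FWHM, 0.5 s) whose within-wave timing decays exponentially
(tau = 0.15 s, so most firings fall in the first ~256 ms of a wave) —
this feeds the initiation rule, site grouping, occurrence maps and the
85-ms firing distribution. A single spread value cannot produce both
regimes, which is why the schedule carries per-row spread.

The raw-intensity forward model is
`F = b + F0 * M(x) * (1 + A(x, t)) + noise`: a uniform non-indicator
background `b`, indicator baseline `F0` on cell footprints `M` (dark
elsewhere, so the darkest-1% background rule and the baseline mask see
realistic dark pixels), each firing adding a separable spatial Gaussian
times a rise–plateau–decay time course whose half-maximum width equals
the scheduled duration, with the event's support restricted to the
firing cell's own footprint (a transient is fluorescence of that cell's
cytoplasm; painting it onto neighbours would leak attenuated ghost
events into their STMaps). Indicator kinetics default to rise 60 ms and
decay 200 ms (GCaMP6f-like single-transient half-decay ~140 ms).
Additive Gaussian noise (SD 0.05 dF/F0) is applied everywhere; Poisson
photon noise, bleaching, indicator saturation, non-rigid tissue motion
and cell-shaped baseline heterogeneity within footprints are
deliberately not modelled in this version. Passing recovery tests
therefore demonstrates correctness of the measurement chain under an
idealised (but reference-calibrated) optical model — not robustness to
every artefact of real recordings.

Pharmacological conditions are phenomenological multipliers
(`applyCondition`: rate, amplitude, duration), plus an optional
wave-independent stochastic site-firing rate (`background_firing_hz`)
for suppressed-pacemaker regimes; there is no biophysical channel
model.

## Numerical choices that matter

- **Sampling.** Default 1.0 um/px: a 36.8-um FWHM event spans ~37 px and
  the smallest site-level features (~3.5 um) remain well above Nyquist,
  at a quarter of the memory of 0.5 um/px. Pixel size is configurable.
- **Detection threshold (`kSd = 4.5`).** The noise SD is estimated per
  pixel from the sub-baseline residual. Because F0 is the p-th temporal
  percentile, that residual is the lower tail of a normal whose mean is
  `-qnorm(p)` SDs above F0; the tail RMS is therefore rescaled by
  `sqrt(1 + a^2 - a dnorm(a) / p)` (`a = -qnorm(p)`) and the threshold
  placed `a + k` SDs above F0. `k` was calibrated on noise-only
  synthetic movies: at the default smoothing, k = 3 admits hundreds of
  noise-born >= 4-px particles per 1000 frames, k = 4 a handful, and
  k = 4.5 about one — and any false particle inside an inter-wave gap
  corrupts wave counting. Signal transients (>= 1 dF/F0) sit far above
  any of these levels.
- **Baseline mask.** Pixels whose F0 falls below 5% of the F0 image's
  robust maximum are indicator-free background: their intensity is
  floored at zero, the noise there is half-truncated (skewed), and no
  dF/F0 is defined. They are excluded from all analysis.
- **Percentile baseline limits.** F0 = the 10th percentile presumes at
  least ~10% quiescence per pixel. At the default 14.9 cpm the duty
  cycle is ~65% and the estimate is clean; above roughly 25 cpm the
  quiescent gap vanishes and any percentile baseline collapses — which
  is why rate-scaling validations stay within the observed 8–22 cpm
  range.
- **Event metrics at half-maximum.** Regions are found at half the map's
  robust maximum (99.5th percentile, so single-cell outliers do not set
  thresholds), but each event's duration and spread are measured at half
  of its *own* peak; otherwise event-to-event amplitude variability
  biases the extents.
- **Sub-frame onsets.** 219 mm/s across a 1.3-mm field separates cell
  onsets by only ~6 ms, a fifth of the 30-ms frame interval. Onsets are
  half-maximum crossings linearly interpolated between frames, refined
  per event against that event's own peak; with a single global level,
  amplitude scatter alone displaces crossings by several ms and destroys
  the distance–onset fit. The regression form (distance on onset) is
  mildly attenuated by residual onset error; recovered velocity is
  typically ~5–10% below the configured value.
- **CTC merge gap 1.0 s.** Safe because inter-wave quiescence is ~1.5 s
  at default kinetics; note the interaction with indicator decay — a
  0.4-s decay constant would leave sub-threshold tails long enough to
  close the gap entirely.
- **Per-cell STMap readouts** are made on cells selected by
  `selectAnalysisCells`: axis in view over +/-25 um around the soma and
  footprint disjoint from other cells, since clipped cells truncate the
  measurable spread and shared pixels carry two cells' fluorescence.
- **Degenerate inputs.** All-constant movies register with zero shift;
  all-zero movies raise an explicit dF/F0 error; flat traces yield no
  onsets; a velocity fit with all onsets equal is flagged unresolved
  (only a lower bound, FOV/frame-interval, is knowable); Tukey/ANOVA of
  identical groups return F = 0.

## Validation by parameter recovery

The test suite and `scripts/acceptance.R` regenerate seeded recordings
and compare the pipeline's recovered quantities with the generator's
configured values: wave frequency (10 x 60-s network movies), event
duration/amplitude/spread (STMaps of the same movies), firing sites per
cell (25 single-cell movies), velocity (10 low-noise 1.3-mm, 20-s
fields at 4 um/px), latencies (8 x 30-s dual recordings), and geometry
(6 rescaled 400 x 400-um fields). The test suite runs the same checks
at reduced size (4 x 30-s movies, 8 single-cell movies, etc.) to keep
the default `R CMD check` footprint small; problem sizes are stated in
the test files. Property suites cover flood-fill equivalence against a
brute-force BFS (and EBImage's 4-connected labeller), the
initiation-rule truth table, occurrence-map conservation, threshold
monotonicity, latency additivity and scale-invariances.

Two measurement identities are worth knowing when reading results: the
latency correlation (R^2 between summed stage latencies and the direct
ICC-to-displacement latency) is exactly 1 whenever latencies come from
matched onset triplets, since the sum is then algebraically identical
to the direct difference; and `frequencyCpm` times the mean
peak-to-peak interval is ~60 by construction on rhythmic recordings —
the package uses the second as a cross-module consistency check, not as
evidence.

## Known limitations

- Rigid translation registration only; contracting-muscle recordings
  with non-rigid motion are out of scope (the reference preparation —
  excised submucosa — avoids them).
- No automatic cell segmentation or axis skeletonisation: STMap axes
  and ROIs come from the user or the generator.
- The generator's optical model is additive Gaussian in the dF/F0
  domain; photon-limited (Poisson) noise, bleaching and saturation are
  absent, so SNR-dependence conclusions require the noise parameters to
  be varied explicitly.
- Conditions are multipliers on rate/amplitude/duration, not channel
  biophysics: recovery under a condition validates the measurement, not
  any mechanistic claim.
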