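---
title: "Comb-based analysis of cardiac optical mapping recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comb-based analysis of cardiac optical mapping recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opticomb)
```

## The problem

Optical mapping films the electrical or calcium activity of a heart or a
cardiac cell culture through voltage- or calcium-sensitive fluorescent
dyes. A single recording is an intensity movie over the tissue surface —
hundreds to thousands of pixel traces, each a train of action potentials
(APs) or calcium transients (CaTs). The analysis task is to segment each
trace into single beats and measure, per beat and per pixel, the baseline,
amplitude, duration at a chosen recovery level (APD80, CaTD80, ...),
recovery time and activation time, and then to assemble those into spatial
maps: activation (isochrone) maps, conduction-velocity fields, duration
maps, alternans maps.

Threshold-based segmentation struggles here: pixel-level signal-to-noise is
poor, baselines drift with photobleaching, and motion artefacts split
transients. opticomb instead exploits something the experimenter almost
always knows — the activation pattern. Under external pacing (or regular
rhythm, or a scripted S1-S2 protocol) the beats arrive at known intervals.

## The comb algorithm

A *comb* is a rigid set of teeth at the expected inter-beat offsets:
uniform (`uniformComb(periodFrames, nFrames)`) for fixed-rate pacing, or
arbitrary (`customComb(intervals)`) for protocols such as S1-S2. The comb
is slid along a trace over every placement that fits inside it, the mean
signal under the teeth is evaluated at each placement, and the placement
with the minimal mean (for minima/troughs) or maximal mean (peaks) wins;
ties go to the earliest placement. Each tooth is then refined by a local
extremum search within `refinementWidthMs` of its position, with the search
window clipped so refined positions stay strictly increasing.

Because the teeth move as one body, the detections are guaranteed to be
spaced according to the known activation pattern (up to the refinement
width). That single property removes the two classic failure modes of
thresholding — spuriously close and spuriously distant detections — and
averaging the signal over all teeth makes the global positioning highly
noise-resistant: in our tests a 20-transient train with Gaussian noise of
half the signal amplitude still yields a median peak-time error of a few
milliseconds at 1 ms/frame.

```{r comb}
fx <- makeTrace(makeTransientTemplate("catSkewed", 10, 89),
                intervalsFrames = rep(100, 19), nFrames = 2000,
                noiseSd = 0.5, seed = 7)
det <- combDetect(smoothTrace(fx$trace, 11, 4),
                  uniformComb(100, 2000), polarity = "peaks",
                  refinementWidthMs = 10, frameIntervalMs = 1)
median(abs(toothPositions(det) - fx$truth$peakFrames))
```

## The multi-wave pipeline

`analyzeMultiwave()` implements the full per-beat pipeline:

1. **Recording clock.** The spatial average trace (over unmasked pixels) is
   low-noise; its peak activations are comb-detected and the *clock
   boundaries* are the midpoints between consecutive peaks. The clock is
   not a per-beat segmentation — it is a global set of bins that lets
   features from different pixels be attributed to the same wave pass. At
   least three wave passes are required (two boundaries = one complete
   bin).
2. **Per-pixel preprocessing.** Optional Savitzky-Golay smoothing (chosen
   because it preserves sharp upstrokes) and polynomial drift removal.
   Drift removal re-adds the original trace mean, so the recording's
   offset — and hence photobleaching across recordings — remains
   observable; the mean is conserved exactly because the least-squares fit
   contains an intercept.
3. **Segmentation.** Voltage-style traces (activation = downward
   deflection, since lower intensity means higher membrane potential) are
   upward-rectified about their median; diastoles (points of least
   activation) are comb-detected and split the trace into single beats.
4. **Feature extraction.** Baseline = first sample of the segment (or mean
   of first and last); amplitude = peak − baseline; duration via
   thresholding at `baseline + (1 − recoveryLevel) · amplitude` with
   linear interpolation at both crossings; recovery time = the
   interpolated end crossing; activation time = the first interpolated
   crossing of half-maximal amplitude. When noise splits a beat into
   several above-threshold objects, one is chosen by `objectSelection`:
   `first`, `largest`, or `augmented` — the object closest to the beat's
   upstroke, where upstrokes are comb-detected on the discrete derivative
   of the *whole* trace, which is far more robust than a per-beat search.
5. **Clock normalisation and binning.** Activation and recovery times are
   converted to global time and the nearest preceding clock boundary is
   subtracted; each record is assigned to the bin containing the segment's
   temporal midpoint ("half-time"), and records whose half-time falls
   outside the clock are dropped as potentially incomplete.

```{r multiwave}
wave <- makePlanarWaveStack(rows = 12, cols = 8, speedPxPerFrame = 1,
                            bclFrames = 100, nBeats = 5)
maps <- analyzeMultiwave(wave$recording, periodFrames = 100,
                         params = traceParams(smoothingWindow = 0,
                                              driftPolyDegree = -1))
maps
round(beatMeanMap(maps, "activationTime")[, 1], 2)
```

The activation map is a clean 1 ms/row ramp — the fixture's ground truth —
and, thanks to the shared clock, the per-beat maps of different wave
passes agree pixel-wise even though every pixel's diastoles differ.

`analyzeSinglewave()` handles one-pass recordings (no comb, no clock, whole
trace = one segment, global times). `analyzeHybrid()` splits a regular
recording into one-cycle substacks starting at the first clock boundary,
averages them frame-wise, and runs the single-wave path on the average:
noise drops roughly as the square root of the beat count, at the price of
all per-beat information — alternans in particular is averaged away, so
multi-wave mode is the right tool there.

## Postprocessing

* `plotActivationMap()` renders filled-contour isochrone maps (minimum
  normalised to 0), writing PNGs only — safe for headless batch use.
* `cvBetweenPoints()` measures conduction velocity between point pairs:
  pitch × pixel distance / activation-time difference.
* `baylyLocalCv()` fits a second-order bivariate polynomial activation
  surface T(x, y) in a square window around every pixel and converts the
  centre gradient g into velocity v = g/|g|². The fit is exact on planar
  waves (linear surfaces). On strongly curved fronts the quadratic is only
  a local approximation: with the default window radius of 3 px a circular
  target wave is biased near its source, while radius 1 recovers the speed
  within ~3% outside a 3-pixel core. Choose the radius by front curvature:
  large windows smooth noise on quasi-planar fronts, small windows track
  curvature.
* `alternansMap()` averages even-pass and odd-pass feature maps and reports
  per pixel the large-to-small ratio max(e,o)/min(e,o), the symmetric
  ratio |e−o|/(e+o) (sMAPE), or 1 − min(e,o)/max(e,o). All three are
  parity-symmetric and algebraically linked (1 − 1/ratio; (ratio−1)/(ratio+1)),
  which the tests verify. The formulas presuppose a positive feature;
  non-positive even/odd means are flagged and dropped.
* `temporalSdMap()` computes the per-pixel SD of a feature across wave
  passes: low where activation is regular, high where the periodic comb is
  forced onto non-periodic signal — a cheap detector of irregular
  activation sites.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `smoothingWindow`/`Order` | 11 frames / 4 | Savitzky-Golay filter; 0 = off |
| `driftPolyDegree` | 4 | polynomial drift removal; negative = off |
| `recoveryLevel` | 0.8 | duration level: 0.8 = APD80/CaTD80 (a fraction, not a percent) |
| `baselineMode` | `"first"` | first sample vs mean of first and last |
| `objectSelection` | `"first"` | `largest` / `augmented` for noisy data |
| `polarity` | `"peaks"` | `peaks` = calcium-style upward, `troughs` = voltage-style downward |
| `refinementWidthMs` | 10 ms | comb local-search half-width; widen for S1-S2 in tissue where diastolic intervals vary regionally |
| `windowRadiusPx` | 3 px | Bayly fitting window; reduce for curved fronts |

The frame interval is always supplied by the user; image metadata is
ignored. Recovery levels are fractions in (0,1); a level below 0.5 makes
the duration object sit entirely above the half-max threshold, in which
case the activation-time search widens from the object to the whole
segment.

## The synthetic generators, and what passing tests mean

All tests run on synthetic recordings with exact ground truth:
`makeTransientTemplate()` builds piecewise-linear "tent" APs (closed-form
features via `analyticTransientFeatures()`) and fast-rise/exponential-decay
CaTs; `makeTrace()` pastes them at known stimulus times with optional
amplitude alternans `1 + a(−1)^k`, polynomial drift, and seeded Gaussian
noise; `makePlanarWaveStack()` adds row-wise propagation at a known speed,
and `makeDiscordantAlternansStack()` builds opposite-phase alternans zones
separated by a nodal row with a linear taper.

These fixtures emulate the signal structure of real recordings —
transient shape asymmetry, pacing regularity, drift, additive i.i.d.
Gaussian noise, alternans, planar propagation — but not everything real
data contains: motion artefacts, spatially correlated noise, dye
saturation, curved and colliding wavefronts, or genuinely arrhythmic
activation. Passing tests therefore demonstrates correctness of the
algorithms under the stated signal model, not performance guarantees on
any particular experimental preparation.

Problem sizes in the tests and the acceptance script are deliberately
modest (grids up to ~21×21 pixels, 20-beat trains, 50 noise replicates):
they are the smallest sizes at which each property is informative, and the
full suite runs in well under a minute.

## Numerical and design choices

* **Indexing and time.** Frames are 1-based in R; time in ms is
  `(frame − 1) × frameIntervalMs`, so frame 1 = 0 ms. Sub-frame times come
  from linear interpolation and are exact on piecewise-linear signals.
* **Ties.** Comb placement ties go to the earliest offset, refinement ties
  to the earliest index, object-selection ties to the earliest object —
  determinism throughout; two identical runs produce bit-identical CSVs.
* **Rectification.** Downward-deflection traces are analysed as
  `2·median − trace`, so every feature definition is written once for
  upward deflections and amplitudes are always positive. The reported
  baseline of voltage-style traces is in rectified units.
* **Half-time.** The bin-assignment "half-time" is the temporal midpoint
  of the segment between its bounding diastoles. (The first half-max
  crossing would be an equally defensible reading; the two differ only for
  activations within half a beat of a clock boundary.)
* **Bin collisions.** If erratic segmentation puts two activations of one
  pixel into one clock bin, the later record overwrites the earlier and a
  warning reports the count.
* **Missing data.** NA is the missing marker everywhere; masked pixels are
  NA in every output layer; CSV writers emit empty cells. A beat whose
  amplitude is non-positive or that never crosses half-max yields a
  missing record rather than an extrapolated one, and one bad pixel never
  aborts a map.
* **Binning.** Spatial binning truncates incomplete edge blocks rather
  than padding (padding would bias edge pixels); a binned mask keeps only
  blocks that were fully analysed.
* **Maximum-contrast image.** Defined here as the per-pixel temporal
  max − min, rescaled to [0, 1] over analysed pixels; a temporally
  constant recording degenerates to all zeros. It is a mask-drawing aid,
  not a quantitative feature.
* **Unknown rates.** The comb requires a known activation pattern; that is
  a real limitation, mitigated by `estimateCustomComb()`, a documented
  heuristic that thresholds the low-noise spatial average trace and builds
  a custom comb from the detected activation intervals.
* **Hybrid BCL.** Substack splitting uses the user-supplied period, not a
  re-estimate from the clock: the pacing rate is treated as experimental
  knowledge.

## Known limitations

Non-periodic arrhythmias are out of scope beyond the temporal-SD
irregularity map; forcing the periodic comb onto chaotic activation
produces poor segmentation by construction (and the SD map exploits
exactly that). JPEG frame folders are not read (TIFF and PNG are). Spatial
filtering beyond per-trace smoothing is intentionally left to the user, as
is any GUI: the interface is functions, config files and the
`inst/scripts/opticomb.R` command line, which is what makes batch
processing and exact reproduction of an analysis trivial.
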