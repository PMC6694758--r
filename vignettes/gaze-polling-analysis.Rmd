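---
title: "Detecting gaze polling in curve driving: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gaze polling in curve driving: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazepoll)
```

## The problem

When drivers negotiate a bend, most of their gaze supports online
steering: it follows the road roughly 1–2 s ahead of the vehicle. These
*guiding fixations* (GF) are interrupted by occasional *look-ahead
fixations* (LAF) — glances far toward the bend exit that serve
anticipation rather than immediate control. *Gaze polling* is the
complete cycle GF area → saccade → dwell in the LAF area → saccade →
GF area. `gazepoll` turns 20 Hz gaze logs of repeated bend traversals
(participants × active/passive driving × speed × bend) into polling
events, per-bend gaze-strategy categories, and the statistics that
summarize them.

The pipeline has five stages, each exposed as ordinary functions and
chained by `run_gaze_analysis()`:

1. **Empirical GF reference** (`estimate_gf_reference()`): the median of
   all participants' horizontal gaze in every 0.5 m arc-length bin,
   smoothed with a third-order Savitzky–Golay filter. The curve defines
   the zero of *eccentricity*; left-bend traversals are mirrored so a
   positive eccentricity always points toward the bend exit.
2. **GF/LAF threshold** (`fit_mixture()`, `derive_threshold()`): a
   univariate Gaussian mixture fitted by EM to the active-condition
   eccentricities of each section, with the number of components chosen
   by BIC. The component nearest zero is the GF component; the
   threshold is its upper quantile at 99.95% coverage,
   `t = mu_GF + z(0.9995) * sd_GF`. Samples strictly above `t` are in
   the LAF area; everything else, including negative eccentricities, is
   GF area.
3. **Segmentation** (`segment_series()`, `classify_segments()`): the
   eccentricity series is parsed into connected linear segments by a
   sequential maximum-likelihood rule and classified by slope
   (fixation ≤ 5°/s < pursuit < 40°/s ≤ saccade).
4. **Event detection** (`detect_events()`, `analyze_polling()`): a
   state machine opens an event at a saccade launched from a GF-area
   sample that lands on a LAF-area sample, merges everything while the
   area stays LAF into a single dwell, and closes at the first saccade
   landing back in the GF area. Per bend section the strategy is
   `polling`, `gf_only`, `laf_only`, or `mixed_incomplete`; polling
   frequency, mean LAF duration, and cumulative LAF percentage are
   computed when at least one event occurred.
5. **Statistics** (`bin_distributions()`, `compare_distributions()`,
   `rm_anova_2x3()`): 31-bin eccentricity distributions (−11° to 18° in
   1° steps plus two extreme classes), per-bin paired *t* tests with
   Holm adjustment across the 31 bins, and 2 × 3 fully-within ANOVAs
   (driving mode × speed) on the polling metrics with partial
   eta-squared effect sizes.

## Analyzed geometry

The track is a 120 m straight approach (section A), a 100 m arc of
100 m radius whose first 50 m are the cornering section C1, and a
100 m exit straight. Positions are arc length in meters from the start
of the approach; sections are half-open intervals (`[0, 120)`,
`[120, 170)`), so every position has exactly one label. At the highest
speed (90 km/h) the approach still takes 4.8 s, leaving the driver at
least 4 s of anticipation time.

## The synthetic generator

No public dataset accompanies the study design, so `simulate_gaze()`
generates gaze logs with the statistical structure the analysis
assumes, together with the latent ground truth (per-sample state,
excursion intervals, true guiding curve) that the test suite uses as an
oracle.

Per traversal, gaze tracks the *guiding azimuth* — the direction of the
point on the future path 1.5 s ahead — with Gaussian tracking noise
(`gf_sigma_deg`, default 1.8°). Look-ahead excursions arrive as a
Poisson process whose rate depends on driving mode, section, and speed;
each jumps via a 50 ms linear ramp to an amplitude drawn from a
mid-eccentric (11° ± 2°) or far-eccentric (24° ± 3°) Gaussian, dwells
for an exponential duration (0.4 s active, 0.7 s passive), and returns.
A small fraction (2%) of excursions target the opposite (scenery) side
so the negative extreme bin of the distribution is exercised.
Per-participant lognormal rate multipliers (SD 0.5 on the log scale)
create the individual variation in polling propensity that the
strategy-map output is meant to display.

Choices worth making explicit:

* **Default rates.** The per-mode, per-section base rates (active
  A 0.11 /s, C1 0.04 /s; passive A 0.16 /s, C1 0.28 /s, scaled
  linearly with speed relative to 75 km/h) were chosen once so that the
  *qualitative* study pattern holds — polling in roughly half the
  approach traversals, rare active cornering polling, frequent passive
  cornering polling. They are generator conditions, not estimates of
  any real quantity.
* **Smooth anticipation.** The raw preview azimuth has corners in its
  derivative where the preview point crosses section boundaries. Real
  gaze anticipates gradually, so the generator tracks the preview
  azimuth convolved with a Gaussian kernel of 10 m arc length
  (`blend_m`). This also matters numerically: a Savitzky–Golay filter
  spanning 31.5 m reproduces a smooth transition faithfully but
  overshoots a kinked one by close to a degree.
* **Entry phase.** Each traversal enters the track at a uniformly
  random sub-sample arc-length offset. Section entries in a real
  simulator are not aligned with the sampling clock; perfectly aligned
  grids would also leave some 0.5 m bins systematically empty.
* **Reproducibility.** All randomness derives from one seed via
  counter-based substreams, so rerunning with the same seed is
  byte-identical and removing participants leaves the remaining
  participants' data unchanged.

What the generator does **not** emulate: vehicle dynamics and steering
corrections, eye-tracker drift and calibration error, blinks, vertical
gaze structure, smooth pursuit of scene objects, and any dependence of
excursion timing on road events. Passing tests on synthetic data
therefore demonstrate that the pipeline recovers the structure the
generator encodes — not that real driving data are this clean.

## Numerical choices

**Reference.** The "31 m" smoothing window is implemented as 63 bins
(31.5 m), the nearest odd bin count covering at least 31 m at 0.5 m
bins; a 31-point reading (15.5 m) remains available through
`window_bins`. Near the curve ends the filter evaluates the polynomial
fitted on the first/last full window, so the reference is defined over
the whole extent. Sample positions are mapped to the reference by
nearest bin rather than interpolation; at 0.5 m bins the difference is
below 0.1° and the exactness simplifies testing. One reference is
fitted for the whole track and restricted to sections afterwards; the
test suite asserts that restriction and per-section evaluation agree.

**Mixture.** The EM runs on eccentricities rounded to a 0.01° grid
(distinct values with multiplicities), which is exact for the gridded
data and keeps 40 000-sample fits fast; component SDs are floored at
0.1° to exclude singular spikes; means are seeded k-means++-style, each
candidate order gets 10 short restarts and the best is polished to
convergence; BIC is `-2 logL + (3k - 1) log n`. The threshold uses the
parametric GF quantile rather than an empirical percentile of
GF-assigned points: at coverage 99.95% the empirical percentile of a
desk-scale sample is dominated by its few largest points, while the
parametric form is stable and round-trips exactly (the GF CDF evaluated
at the threshold returns the coverage to 1e-9).

**Segmentation.** The sequential rule keeps a running least-squares
line per segment and tests each incoming sample with the exact
likelihood-ratio between *extend* and *open a new segment*, expressed
as the residual sum-of-squares increase `r² / (1 + h₀)` against
`2 · split_penalty · noise_sd²` (`r` the prediction residual, `h₀` its
leverage). Three refinements matter at 20 Hz:

* a new segment is *anchored* at the previous sample, so a jump between
  consecutive samples forms its own steep segment (the connected
  polyline of segmented-linear-regression approaches);
* a segment whose fitted slope is already saccadic (≥ 40°/s) is closed
  at the next sample — saccades span at most two samples at this rate,
  and without this rule the line through a jump absorbs the following
  dwell as a spurious pursuit;
* freshly opened (two-point, anchored) segments test the raw residual
  of their determined line, and a split may be moved back one sample
  when the previous sample already sat off the line on the same side.
  Both keep the samples right after a gaze shift from being swallowed
  by leverage discounting.

The residual noise SD defaults to a robust estimate from the lower
quartile of absolute second differences — blind to linear trends and
barely touched by the jump-contaminated tail — pooled across all
traversals in `segment_traversals()`, since tracker noise is a device
property while per-traversal estimates are inflated on
excursion-dense traversals. The fixed 0.8° value remains available by
passing `noise_sd` explicitly. Scale equivariance holds in the
dimensional sense: multiplying the signal, `noise_sd`, and the (°/s)
saccade threshold by the same constant leaves the boundaries unchanged.

**Detection.** An event's section is the section where its outbound
saccade starts, keeping per-section counts disjoint even when dwells
span the A/C1 boundary. Excursions still open when the record ends are
not events (the cycle must complete), and one-way crossings yield the
`mixed_incomplete` category, reported separately rather than forced
into the three-way taxonomy. Dwell membership requires at least one
sample; no minimum dwell duration is imposed.

**Statistics.** Paired comparisons pool speeds within participant;
degenerate tests (zero-variance differences, typical for empty extreme
bins) are excluded from the Holm family, shrinking it. The ANOVA drops
participants with any missing cell for a metric listwise and records
the count; in this balanced within-subject design the Type III
decomposition coincides with the classical partitioning, and
`F` statistics are checked against a brute-force definitional
sums-of-squares oracle to 1e-8. Partial eta-squared is
`SS_effect / (SS_effect + SS_error)`; `r²` for paired tests is
`t² / (t² + df)`.

## What the test suites run

The property suites use problem sizes chosen to probe each claim
without redundancy: the full default design (18 × 6 × 2 × 3, one
simulation shared across checks) for coverage, threshold round-trip,
and event-count agreement; 20 replicated full designs for threshold
stability against the GF-state quantile; 500 replicates of an 18 ×
1-bend null design (identical active and passive settings) for
family-wise error of the 31-bin Holm family; 200 replicates with the
passive rate doubled for the power check of the exceedance comparison;
and a 6 × 2 benchmark with fixed 10° excursions at the segmentation
model's canonical 0.8° noise for saccade sensitivity and precision.

## Limitations

* The greedy single-pass segmentation is a simplification of penalized
  exact segmentation; with 1.8° tracking noise a 10° jump is a ~5.5 σ
  event per sample, and a minority of excursions whose realized
  eccentricity hovers near the threshold are genuinely ambiguous.
  Sustained smooth pursuit faster than 40°/s would be fragmented by the
  saccade-closure rule; the bend-relative signal in this design does
  not contain such pursuit.
* The pooled reference cannot remove speed-dependent preview geometry;
  that dispersion is part of the GF spread by construction, in the
  synthetic data as in the design it emulates.
* Per-participant thresholds, vertical gaze, skew-normal or
  nonparametric mixtures, and linking events to steering are out of
  scope.

## A minimal run

```{r example, eval = FALSE}
track <- track_spec()
sim <- simulate_gaze(gaze_gen_spec(), track, seed = 1)
res <- run_gaze_analysis(sim$log, track)
res$thresholds
tally_strategies(res$outcomes)$counts
build_report(res, "gazepoll-report", seed = 1)
```
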