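---
title: "Quantifying mitotic spindle phenotypes with spindlemetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitotic spindle phenotypes with spindlemetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlemetrics)
```

# Scope and model

`spindlemetrics` quantifies mitotic-spindle phenotypes from multi-channel
fluorescence microscopy: chromosome alignment, spindle length, the angle of
the pole axis to the focal plane, spindle rotation, peripheral-versus-spindle
intensity ratios, single-molecule motor velocities from kymographs, and
mitotic timing. Each assay is a deterministic measurement on a calibrated
image (or event table); a synthetic-microscopy generator with a full
ground-truth manifest backs every measurement with recovery tests.

All positions use 0-based pixel indices referring to pixel centers; physical
positions are `index * pixel_size_xy` (or `slice * z_step`). Intensities are
treated as unitless non-negative reals — camera bit depth is deliberately
not modeled. Arrays are normalized internally to `(channel, time, z, y, x)`
order. Calibration comes from a config that overrides any file metadata,
because fixed-cell and live assays are typically acquired on different
optics; an operation that needs a missing calibration field fails naming the
field rather than assuming a default.

# Chromosome alignment (FWHM)

The alignment metric is the full width at half maximum of a Gaussian fitted
to the kinetochore fluorescence profile along the pole-to-pole axis. The
profile is sampled at unit-pixel spacing by bilinear interpolation, averaged
over a 20 px width perpendicular to the axis, normalized internally to its
highest value, and fitted with

$$ I(x) = A \exp\!\left(-\frac{(x-\mu)^2}{2\sigma^2}\right) + c,
   \qquad \mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma . $$

A smaller FWHM means kinetochores cluster more tightly at the metaphase
plate. Choices that matter:

* **Offset term `c`.** On by default: real backgrounds are nonzero, and
  omitting the offset biases $\sigma$ on elevated baselines. `offset = FALSE`
  restores the pure Gaussian.
* **Initialization and bounds.** $A = \max - \min$, $\mu$ = intensity-weighted
  centroid, $\sigma$ = span/6, $c = \min$, with $\sigma \in (0,
  \text{span}]$. Because a profile of discrete kinetochore puncta is jagged,
  the Levenberg–Marquardt fit is restarted from $\sigma \in
  \{\text{span}/12, \text{span}/6, \text{span}/3\}$ and the lowest-SSE
  solution kept; single-spike local minima are the failure mode this guards
  against.
* **QC.** Non-convergence or $R^2 < 0.5$ flags the record (`qc_pass`);
  nothing is dropped silently. An unidentifiable fit (constant profile)
  reports `converged = FALSE`, never a silent `NaN`.
* **Line width.** The profile width (20 px) mirrors the width used by the
  localization line scan, for consistency across assays; it is configurable.

**Identifiability.** The profile window is the pole-to-pole segment, so the
estimator is only informative while the window covers the kinetochore
distribution. With a free offset, spreads wider than roughly a third of the
spindle length become unidentifiable (the fit drifts to its $\sigma$ bound).
Recovery cohorts therefore co-scale spindle length with spread,
$L = \max(10, 6\sigma)\,\mu m$, keeping the window at $\pm 3\sigma$ —
consistent with the biology, where severely unaligned cells also have longer
spindles.

# Spindle geometry and rotation

Poles are the two brightest well-separated maxima of the pole channel
(maximum projection for z-stacks), refined by the intensity centroid of a
5×5 window; for z-stacks each pole takes the slice of maximal in-focus
intensity. Manually clicked `(x, y, slice)` triplets can be supplied through
`pole_pair()` — automatic and manual paths share all downstream math.

The pole-axis angle converts the inter-pole vector to micrometers first
(z via `z_step`; with 0.25 µm steps against ~0.11 µm pixels, raw-index
angles would be meaningless) and takes the dot-product angle between the
vector and its xy-projection, in [0°, 90°]. It is invariant to xy-rotation
and to pole order.

Rotation is quantified by tracking one pole frame-to-frame
(nearest-maximum linking within a 2 µm radius, ties broken by brightness)
and reporting the **full polyline path length divided by elapsed minutes**.
Path length matches what interactive track-measurement tools report, but it
differs from net start-to-end displacement for wobbling spindles — with
tracking noise it is strictly positive even for a stationary pole
(≈0.04 µm/min at 0.2 px noise, 0.108 µm/px, 1 min/frame), so stationary
baselines should be compared, not assumed zero.

# Intensity ratios

Band ROIs are built with the Euclidean distance transform, giving an
isotropic ring of the stated physical width (2.5 µm for the EB1
polymerization assay, 4.5 µm for tubulin density) around the inner ROI —
never a square structuring element, since the width is specified in
micrometers. Inner ROIs may be supplied as masks or derived by Otsu
thresholding plus largest-component selection; the background ROI is either
supplied or chosen as the darkest 32×32 tile free of foreground.

* `band_ratio()` is a pure ratio by default (no background subtraction),
  with subtraction available via `background_roi` — use it whenever the
  acquisition has a nonzero camera offset, since an additive offset biases
  a pure ratio toward 1.
* `tubulin_density()` reports background-subtracted spindle and peripheral
  means separately, as each is compared across conditions on its own.
* `expression_level()` divides the background-subtracted spindle mean by
  the control-condition mean, so the control cohort averages 1 by
  construction.
* `linescan_quartile_ratio()` samples a 20 px-wide line, centered on the
  kinetochore mass and twice its length, rescales positions to [0, 1] and
  divides the mean over the outer quarters by the mean over the middle
  half. Boundaries are exact quarters with half-open intervals
  ([0, 0.25) and (0.75, 1] peripheral); samples landing exactly on 0.25 or
  0.75 count as spindle. Published descriptions sometimes print "0.74–1"
  for the top quarter; this is treated as rounding of the exact quarter.

All ratios are exactly invariant to multiplying the image by a positive
constant, and background subtraction is exactly invariant to adding one.

# Kymograph velocities

`build_kymograph()` reads a time lapse along a segment (row = frame,
column = position; a segment of length $L$ px yields $\lceil L\rceil + 1$
columns). Two estimators are reported per run:

* `velocity_rect` — the manual bounding-rectangle rule:
  $(\text{width}_{px} \times \text{pixel size}) /
  (\text{height}_{frames} \times \text{frame interval})$, with width
  = (max − min integer ridge column) + 1 and height = frames spanned. The
  ±1 px convention materially changes short-run velocities, which is why it
  is fixed and documented; the rule is exactly linear in pixel size and
  inverse in frame interval.
* `velocity_fit` — the least-squares slope of the sub-pixel ridge
  (intensity-weighted column per frame), which is unbiased down to slow
  velocities where the rectangle quantization dominates.

Automated detection thresholds the kymograph (mean + 2 SD by default),
labels connected traces, and splits each trace where the ridge retreats
≥ 2 px from its running extremum — a reversal criterion robust to sub-pixel
jitter that a per-frame slope-sign rule would mistake for direction changes.
Runs shorter than 5 frames or moving less than 2 px are discarded as
stationary clutter. An empty kymograph returns an empty run list, not an
error. Manual measurements (user-drawn rectangles) are supported through
`rectangle_velocity()` directly.

# Mitotic timing and statistics

Durations are `(anaphase − NEB) × frame interval` (e.g. 3 min/frame).
A cell with NEB but no anaphase is **arrested** if at least 60 min of movie
remained after NEB, and **censored** (excluded from both the duration and
the arrest tallies) otherwise; arrested + divided + censored always
partitions the cells. The arrest fraction is arrested / (divided +
arrested). The 60 min window is the conventional "entered mitosis at least
an hour before the movie ended" rule and is configurable.

`compare_groups()` is a thin reporting layer: one-way ANOVA with Tukey's
HSD (parametric family) or Kruskal–Wallis with Dunn's all-pairs rank
comparison (nonparametric). Dunn's z-tests are computed directly from the
rank-sum formulation with tie correction; the pairwise adjustment defaults
to Holm. Statistics run on per-cell values; per-replicate means are
reported alongside for superplot-style figures. Which family applies is an
assay-level choice (alignment, angle, rotation and the ratio assays are
conventionally parametric; timing and tubulin density nonparametric).

# The synthetic generator

The generator renders idealized fixtures whose every parameter is recorded
in a `GroundTruthManifest`, making all measurements testable by recovery:

* **Bipolar cells** — two pole spots at the manifest positions (the manifest
  `spindle_length` always equals their Euclidean separation), kinetochores
  drawn Normal(midpoint, spread σ) along the axis with truncated-normal
  lateral offsets, an elliptical tubulin body with an optional peripheral
  shell scaled by `peripheral_to_inner_intensity`, and a GFP channel with
  inner/outer zones along the axis for the line-scan assay. Defaults:
  256×256 px at 0.1083 µm/px (60×-like), 10 µm spindle, 92 kinetochores
  (both sisters of 46 chromosomes), kinetochore spots rendered at σ = 3 px
  (an extended object, wider than the bare PSF).
* **Monopolar cells** — one pole, a DNA disk (4 µm default), EB1 puncta at
  independent densities inside the disk versus the surrounding 2.5 µm band.
  A 0.5 µm margin annulus continues the band density beyond the band so the
  measured ring is not biased by an artificial drop to zero at its outer
  edge. The monopolar default background is zero because the band assay is
  a pure ratio; simulating a camera offset is meaningful only together with
  background subtraction.
* **Rotation movies** — a rigid rotation about the spindle centroid
  (default 31 frames at 1 min/frame), with true per-frame pole positions in
  the manifest; frame *t* is exactly the rotation matrix applied to frame 0.
* **Kymographs** — constant-velocity bright ridges on a uniform background
  (default 200 frames × 80 px at 0.1 s/frame and 0.1 µm/px, matching a
  10 frames/s acquisition), with per-run truth in the manifest; SNR is peak
  amplitude over noise SD.

The PSF is an isotropic 2D Gaussian (σ = 1.3 px) — adequate for centroid,
ratio and fit recovery without optics modelling. Noise is Poisson shot
noise on signal + background followed by Gaussian read noise (SD 2), both
switchable off for exact tests. Random streams are split per channel from
the manifest seed by a fixed rule, so adding a channel never perturbs
another channel's realization, and identical (seed, manifest) gives
bitwise-identical output.

**What the generator does not emulate** — and hence what passing recovery
tests do not establish about real data: realistic chromosome morphology,
3D PSFs, photobleaching, spatially varying background, segmentation
ambiguity on dim or crowded cells, and out-of-focus light. Two quantified
artifacts of the idealization are worth knowing: PSF mixing at the
inner/band boundary pulls band ratios toward 1 by up to ~8–10 % at 4-fold
contrast (the same physics affects real ROI ratios), and rasterized zone
edges bias the line-scan ratio a few percent toward 1 at high contrast.

# Problem sizes and numerical choices

Recovery studies in the test-suite and acceptance script use cohorts of
50 cells per spread level (alignment), 20 cells per enrichment level
(ratios), 25 runs per velocity level, and 100 repetitions of 15-cell
rotation cohorts — sizes chosen to hold standard errors a few-fold below
the tolerances they check while keeping a full run in the low minutes on a
laptop. Ties in pole detection are broken by brightness; fits that fail
report diagnostics; degenerate inputs (empty ROI, all-zero profile,
coincident poles, zero-puncta ratio) raise errors rather than propagate
NaNs.
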