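---
title: "Methods: kymograph velocimetry, branching fits and morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kymograph velocimetry, branching fits and morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vascflow quantifies blood flow and architecture in transparent, extracorporeal
vascular networks — the kind found in colonial ascidians such as *Botryllus
schlosseri*, whose vessel bed is embedded in clear tunic and is directly
imageable in vivo. This vignette is the package's own account of the methods:
the models, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The measurement chain

A vessel is recorded as a single-channel time-lapse stack with spatial
calibration (µm/px) and temporal calibration (s/frame). The analysis chain is:

1. **Kymograph** (`extract_kymograph`). A polyline ROI drawn along the vessel
   center line is resampled at 1-px arc-length steps; intensity is sampled by
   bilinear interpolation and averaged across the ROI thickness (default 3 µm,
   at 1-px steps along the local normal, spanning ± thickness/2). The result
   is a time × axial-position matrix: moving cells appear as sloped streaks,
   immobile objects as vertical stripes.
2. **Normalization** (`normalize_kymograph`). Static structure is removed per
   position column by subtracting that column's rolling temporal average
   (default window 20 frames), then the whole matrix is standardized to mean
   0, SD 1. The rolling window runs over *time within each column*, because
   its purpose is to cancel vertical stripes; at the first and last frames the
   window shrinks symmetrically rather than discarding frames, so short
   recordings keep their full length.
3. **Velocimetry** (`estimate_velocity_trace`). For every timepoint a local
   section of 3 frames is taken; for each candidate signed shift
   *s* ∈ [−max_shift, +max_shift] the Pearson correlation between row pairs
   one frame apart (second row displaced by *s*) is averaged over the section.
   The shift maximizing this curve gives the per-frame displacement and
   *v* = Δx/Δt, converted with the calibration. The correlation magnitude at
   the peak gates the estimate: timepoints with peak correlation ≤ 0.8 carry
   no velocity, which excludes particle-free, noise-dominated stretches. We
   use the mean Pearson coefficient as the "correlation magnitude" because it
   is bounded in [−1, 1], which is the scale on which a 0.8 threshold is
   meaningful; an unnormalized cross-correlation would need a data-dependent
   cutoff.
4. **Per-vessel summary** (`summarize_vessel_velocity`). The maximum speed
   over valid timepoints (the quantity plotted against diameter in branching
   analyses), the median speed, the valid fraction, and the number of flow
   reversals — sign changes between consecutive valid nonzero velocities;
   exact zeros do not break a run.
5. **Diameter** (`measure_diameter`). On the minimal projection (per-pixel
   minimum over time; passing cells darken the lumen) the intensity profile
   along a cross-vessel line is measured as full width at half minimum. The
   baseline comes from the outer 10 % of samples at each end; crossings of
   the half-depth level are located by linear interpolation. We take the
   *outermost* crossings (first from each profile end): for a clean unimodal
   dip this equals the textbook definition, and it is robust to texture
   inside the lumen, where cell tracks are darker than the vessel floor. The
   measurement is invariant to affine intensity transforms. A fully manual
   mode returns the polyline length (`method = "endpoints"`).
6. **Volumetric flow and branching fit** (`volumetric_flow`,
   `fit_branching_exponent`). Q = v·πd²/4 under the default plug profile
   (a parabolic Poiseuille profile halves it). The branching exponent is the
   OLS slope of log Q on log d across vessels; any constant profile factor
   shifts the intercept only, so the exponent is model-independent. A network
   optimized in the sense of Murray's law has exponent 3.

Alongside the flow chain, three self-contained quantifications share the same
statistical kernels:

- **Morphometrics** (`segment_boundary_image`, `compute_shape_metrics`,
  `compare_shapes`): cell area (pixel count × pixel size²) and circularity
  4πA/P², 1 for a perfect circle.
- **Fluorescence** (`compute_ctf`): corrected total fluorescence, integrated
  ROI intensity minus ROI area × mean background. "ROI" in that formula is
  read as ROI *area*, the standard convention; constant offsets cancel
  exactly.
- **Regression scoring** (`bed_size`, `percent_regression`): vascular-bed
  size S = p_ampullae − p_body from traced border perimeters, and percent
  regression 100·(S_ctrl − S_regres)/S_ctrl. The bed "size" is dimensionally
  a length; the formulas are implemented as defined rather than substituting
  an area metric, so results are comparable with measurements made the same
  way. Perimeter unit tags must match and are never inferred.

## The perimeter estimator

Circularity hinges on an unbiased perimeter. Counting pixel-edge steps
overestimates oblique boundaries by up to a factor 4/π, which would give a
disk a circularity near 0.79 and break the defining anchor of the metric; a
Crofton-style estimator with a small number of directions is biased the other
way on axis-aligned edges and misses the package's own square anchor. We
instead extract the sub-pixel marching-squares contour at the 0.5 level
(`grDevices::contourLines`) and smooth the closed vertex chain with a
circular moving average (window 7) before summing edge lengths. The smoothing
removes the staircase that makes the raw marching-squares polygon ~5 % too
long on oblique boundaries, while a 7-vertex window is short enough to leave
true corners nearly intact. The acceptance checks pin this down: a rasterized
disk of radius 200 px must score 1.00 ± 0.02 and a 200-px square π/4 ± 0.02.
Raw circularity can exceed 1 by a fraction of a percent on small labels
(discretization); the clamped and raw values are both reported.

## Statistics

Group comparisons use two-tailed t-tests: pooled-variance two-sample by
default (Welch by flag), and a paired design for before/after or
control-vs-regenerated layouts. Reported group spreads are SEM (mean ± SEM
is the reporting convention for the cell-shape comparisons this package
serves; SDs are also returned). Power-law fitting is OLS on log-log data.
Computation is delegated to R's `t.test`, `pt` and `lm`; the test suite
verifies every statistic against brute-force closed-form oracles to 1e-10
and checks the empirical type-I error (0.05 ± 0.01 over 10,000 null
simulations). Degenerate inputs follow a fixed convention: zero variance
with equal means returns t = 0, p = 1; zero variance with unequal means is
an error. Non-finite observations are rejected, never silently dropped.

## What the synthetic generators emulate

`simulate_vessel_movie` renders a straight vessel segment: Gaussian-blob
particles (σ = `particle_radius_px`) advected along the axis at a constant or
per-frame signed velocity, immobile speckles, an axial illumination gradient,
an optionally darkened lumen, and i.i.d. Gaussian camera noise. Particles
wrap periodically at the segment ends so the particle density — and hence
kymograph statistics — is stationary in time. Reversal fixtures encode the
velocity profile as a per-frame signed sequence, so the estimator is
exercised on sign changes. All randomness derives from one explicit seed per
call and the global RNG state is restored afterwards; identical parameters
and seed give bit-identical output.

Default conditions: 300 frames at the reference calibration 0.313 µm/px and
0.177 s/frame, a 256 × 40 px lumen, particle contrast 60 over background 100,
noise SD 4. The default particle density, 30 per 100 px of vessel length,
reproduces the dense streak coverage of a young vessel's kymograph (about 15
particles within a 3-µm center line); old, cell-poor vessels are emulated by
lowering it. No imaging study reports these densities numerically, so they
are set by that phenomenological target and exposed in the configuration.

What the movie generator does **not** model: pulsatile flow from a beating
heart, cell–cell interactions and non-uniform velocity profiles across the
lumen, 3-D vessel geometry, focus drift, and photobleaching. Passing the
recovery tests therefore shows the estimator is correct for advected
high-contrast particles under stationary noise — not that it is robust to
every artifact of live microscopy.

`simulate_murray_network` builds a symmetric bifurcating tree with
d_child = d_parent · k^(−1/n) for k children and branching exponent n, equal
flow splitting (so ΣQ_child = Q_parent exactly, by construction), and
v = Q/(πd²/4). Multiplicative lognormal noise (sdlog = `noise_sigma`,
median-unbiased) is applied to the *reported* diameter and velocity, and the
reported Q is recomputed from those noisy values — mimicking independent
measurement error in the two observables. Defaults: 5 levels, root diameter
60 µm, root velocity 300 µm/s, 5 % noise.

`simulate_cell_mosaic` places non-overlapping ellipses (≥ 1 px separation)
with lognormal areas (given mean and CV) and a fixed major/minor ratio; the
ground-truth table carries each cell's intended area and the closed-form
circularity of its generating ellipse (Ramanujan perimeter).
`simulate_bed_outlines` builds a lobed ampullae border and a smooth body
border, then rescales the treated ampullae border about its centroid so the
bed size shrinks by exactly the requested fraction — polygon perimeters
scale linearly under similarity, so the construction is exact.

## Numerical choices and conventions

- Arrays are `(time, y, x)`; coordinates are 1-based with pixel centers at
  integer indices, matching R's native indexing. The x axis is the vessel
  axis.
- Polyline sampling uses bilinear interpolation; nearest-neighbor sampling
  aliases streak slopes on oblique ROIs.
- Argmax ties in the correlation curve resolve toward the smaller |shift| —
  under ambiguity the estimator prefers "no flow". Sub-pixel refinement
  (three-point parabola around the integer peak, default on) reduces
  quantization at speeds below ~1 px/frame; the gate always uses the
  integer-lag peak value.
- `max_shift_px` defaults to 15. Per-frame displacements beyond the search
  range are unmeasurable, which is a real acquisition constraint: at the
  reference calibration a 300 µm/s vessel moves ~170 px/frame, so
  `simulate_network_movies` "acquires" its movies at a 4-ms frame interval,
  keeping the fastest segment near 4 px/frame. On a real microscope the
  same consideration dictates the camera frame rate.
- Rendered network movies scale particle count with lumen width (a wider
  vessel carries proportionally more cells) and darken the lumen by 80
  intensity units so the minimal projection carries the full vessel
  silhouette; margins scale with width so the diameter baseline always lies
  in background.
- The end-to-end pipeline isolates failures per vessel (skip and log) rather
  than aborting: low-contrast vessels are excluded exactly as they are in
  practice. Every output file records an MD5 hash of the analysis
  configuration (output paths excluded from the hash).
- Diameter bands for velocity comparisons are closed-open [lo, hi).
- A fully regressed bed (p_a = p_b) has size 0 and percent regression 100;
  p_a < p_b is rejected as a geometry error.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to finish in minutes on one CPU: 300-frame movies with
256-px segments for velocimetry recovery (speeds 0.5–4 px/frame), 5-level
binary trees (31 segments, 20 replicates) for exponent recovery, 512-px
images for the shape anchors, 10,000 null simulations for test size, and a
12-vessel rendered network (150 frames each) for the full-chain recovery of
the branching exponent within [2.7, 3.3].

## Known limitations

- The velocimetry assumes quasi-constant velocity within each 3-frame
  section; strong acceleration inside a section biases the estimate toward
  the section average, and the timepoint at a sharp reversal may be gated
  out or report an intermediate shift.
- Speeds are capped by the shift search range; aliasing from periodic
  particle spacing can in principle produce sidelobe matches, though random
  spacing makes this rare.
- FWHM diameters assume the lumen is darker than the background in the
  minimal projection and that the cross ROI reaches clear background on both
  sides.
- The circularity estimator is validated for labels larger than ~20 px
  across; below that, contour smoothing noticeably rounds corners and the
  raw value can exceed 1.
- Segmentation is a thresholded connected-components partition intended for
  clean boundary stains (and the synthetic mosaics); faint or broken
  membranes would need a gradient-based watershed upstream.
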