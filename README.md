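# vascflow

Quantitative image analysis for transparent vascular networks imaged in
vivo — the extracorporeal vessel beds of colonial ascidians such as
*Botryllus schlosseri*, where aging manifests as vessel narrowing, slowed
blood flow, flattened vascular cells and a blunted regression response.
vascflow turns calibrated time-lapse microscopy and traced outlines into the
quantities those studies compare:

- **Kymograph velocimetry.** A kymograph is built along a manually drawn
  vessel center line, static stripes are removed by per-column rolling-average
  subtraction (20-frame window) and global standardization, and signed flow
  velocity is estimated per timepoint as the shift Δx maximizing the mean
  correlation between kymograph rows one frame apart (v = Δx/Δt). Timepoints
  whose peak correlation does not exceed 0.8 are gated out as particle-free.
- **Vessel diameter and Murray's law.** Diameter is the full width at half
  minimum of a cross-vessel profile on the minimal projection. Volumetric
  flow Q = v·πd²/4 (plug profile; Poiseuille available) is fitted against
  diameter by OLS on log–log axes; the slope is the *branching exponent* n,
  predicted to be 3 for a transport-optimal network (Murray's law).
- **Cell morphometrics.** Area and circularity 4πA/P² of boundary-stained
  vascular cells, with a sub-pixel perimeter estimator calibrated so a disk
  scores 1.
- **Fluorescence.** Corrected total fluorescence,
  CTF = integrated intensity − ROI area × mean background.
- **Regression scoring.** Vascular-bed size S_vb = p_ampullae − p_body from
  traced borders and percent regression 100·(S_ctrl − S_regres)/S_ctrl.
- **Statistics.** Two-tailed two-sample and paired t-tests (pooled or
  Welch), mean ± SEM summaries, log–log OLS.

Every stage has a synthetic counterpart with known ground truth —
particle-advection vessel movies (including flow reversals and immobile
speckles), flow-conserving bifurcating networks with a set branching
exponent, non-overlapping cell mosaics, and before/after bed outlines — so
the whole chain is validated by parameter recovery.

## Worked example

```r
library(vascflow)

# 1) a young-vessel movie whose flow reverses halfway through
profile <- c(rep(2, 150), rep(-2, 150))        # px/frame, sign flips mid-movie
movie <- simulate_vessel_movie(flow_sim_params(velocity_profile = profile,
                                               seed = 42))
roi   <- line_roi(data.frame(x = c(5, 251), y = c(20.5, 20.5)))  # center line
kymo  <- normalize_kymograph(extract_kymograph(movie, roi))
trace <- estimate_velocity_trace(kymo)
str(summarize_vessel_velocity(trace))
#> List of 5
#>  $ v_max_um_s    : num 3.81
#>  $ v_median_um_s : num 3.54
#>  $ valid_fraction: num 0.997
#>  $ n_valid       : int 297
#>  $ n_reversals   : int 1
```

The true speed is 2 px/frame = 2 × 0.313/0.177 ≈ 3.54 µm/s at the default
calibration; the median valid estimate lands on it, 99.7 % of timepoints
pass the 0.8 correlation gate, and the single programmed flow reversal is
detected exactly once.

```r
# 2) branching exponent of a noisy Murray network (true exponent 3)
net <- simulate_murray_network(murray_net_params(seed = 1))
fit_branching_exponent(net)
#> branching exponent n = 2.943 +/- 0.047 (r^2 = 0.993, 31 vessels)

# 3) segment a boundary-stained mosaic and measure cell shape
mosaic <- simulate_cell_mosaic(shape_sim_params(n_cells = 80, seed = 1))
img    <- boundary_image_from_labels(mosaic$labels, noise_sigma = 5, seed = 1)
cells  <- compute_shape_metrics(
            segment_boundary_image(img, 0.25, min_area_um2 = 2), 0.25)
round(colMeans(cells[, c("area_um2", "circularity")]), 3)
#>    area_um2 circularity
#>      31.530       0.988

# 4) score an induced vascular regression from traced outlines
out <- simulate_bed_outlines(0.964, seed = 1)
percent_regression(measure_bed(out$control), measure_bed(out$treated))
#> [1] 96.4
```

The mosaic was generated with mean cell area 31 µm² and mild elongation; the
measured means recover both. The outline pair was constructed to lose 96.4 %
of its bed size, and the scoring chain returns exactly that.

`run_flow_pipeline()` composes the whole flow chain (kymograph →
velocimetry → diameter → Q → exponent fit) over a list of stacks and ROIs,
skipping and logging vessels that fail any stage, and stamping every output
with a hash of the configuration. A thin command-line wrapper over the same
functions ships in `inst/cli/vascflow.R`.

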