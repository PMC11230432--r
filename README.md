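# nucgrowth

Nuclear growth trajectory analysis for multi-day timelapse imaging of human
induced pluripotent stem cell (hiPSC) colonies.

## The problem

In epithelial hiPSC colonies imaged every 5 minutes for days, each nucleus
forms after mitosis, swells rapidly for ~40 minutes, grows slowly for ~15
hours, and breaks down at the next mitosis. Quantifying how nuclear volume
grows — and which parts of that behaviour are inherited from the mother
versus imposed by the local colony environment — requires a chain of
analyses: linking per-frame nuclear detections into tracks, rejecting
segmentation artefacts, locating the expansion-to-growth transition in each
trajectory, fitting the growth shape, measuring local density and colony
geometry, and comparing related nuclei against matched unrelated controls.
`nucgrowth` implements that chain for anyone working with per-nucleus
per-frame feature tables (track id, centroid, volume, height), together
with a synthetic colony simulator that provides ground truth for every
stage.

## The models at the core

* **Tracking** is a minimum-cost assignment between consecutive frames.
  Detections in frames *t* and *t*+1 are nodes; each also has a virtual
  partner (track birth/end) at fixed cost; link cost is
  `dist/d_max + λ·|ΔV|/mean(V)`, links are inadmissible beyond `d_max` or a
  relative volume difference of 0.4. A second round closes gaps of up to 3
  frames. Solved exactly by a shortest-augmenting-path assignment solver.
* **Trajectory QC**: tracks shorter than 5 frames are dropped; volumes
  deviating >15% from a 15-frame centred rolling median (asymmetrically
  padded) are flagged; full-interphase trajectories need formation,
  breakdown, a valid transition, ≥120 frames and non-negative growth.
* **Start of growth**: the first 40 frames after formation are min-max
  normalized, resampled uniformly in arc length, and fit to a hyperbola
  written as the implicit conic `(y − m₁x − c₁)(y − m₂x − c₂) = k`; the
  transition is the data abscissa whose hyperbola point is nearest the
  asymptote intersection, refined by local two-line intersection and
  snapped to a valid frame.
* **Growth shape**: `V(t) = V_start + r·t^α`, nonlinear least squares with
  α ∈ [0.2, 3] (α = 1 linear, α > 1 super-linear); transient growth rate
  `ΔV/ΔT = (V(t+ΔT/2) − V(t−ΔT/2))/ΔT` with ΔT = 4 h.
* **Colony context**: Delaunay/Voronoi adjacency; local density
  `1/mean(neighbour distance)²`; normalized distance from colony centre
  `d_N = (d_max − d)/(d_max − d_min)` from breadth-first graph depth
  (boundary depth 1); radial height slope by OLS; colony-time alignment by
  minimising the mean squared difference of mean-height series over
  integer lags; a hexagonal-prism packing model (`Volume = 3ash`,
  `radius = s√3/2`, nuclear-to-cell volume via NC ratio 0.28).
* **Adder statistics**: added volume is independent of starting volume and
  `CV(added)/CV(ending) → √3 ≈ 1.73` at the steady state of
  `V' = (V + ΔV)/2`; fold-change is negatively coupled to starting volume
  (r ≈ −0.52 for the study's printed moments).
* **Lineage inheritance**: sister and mother–daughter pair correlations
  vs spatiotemporally matched unrelated control pairs (born <10 min and
  <60 μm apart, starting volumes within 80 μm³ for control sisters;
  60 min/60 μm/60 μm³-of-half for control mother–daughter), with
  500-resample bootstrap 90% confidence intervals; a feature is inherited
  when the true-pair and control-pair CIs do not overlap.
* **Colony area**: bright-field z-stack → per-slice CV profile finds the
  focal slab → SD projection → 5×5 Sobel → threshold 0.025 → remove
  objects <734 μm² → fill holes → Gaussian smooth → area at 0.271 μm/px.

## Worked example

```r
library(nucgrowth)

sim <- simulate_colony(sim_config(n_founders = 40, n_frames = 450, seed = 2))
set.seed(2)
res <- run_pipeline(sim$features, sim$lineage, retrack = FALSE)
s <- res$summaries

mean(s$fold_change)          # 2.04  -- nuclear volume doubles on average
density_mode(s$fold_change)  # 2.00  -- peak of the fold-change distribution
mean(s$growth_duration_h)    # 14.9  -- hours from transition to breakdown

ap <- adder_panel(s)
ap$cv_ratio                  # 1.78  -- CV(added)/CV(ending), near sqrt(3)
ap$correlations
#            feature      r         p   n
#        fold_change -0.64   4.4e-17 135   (smaller nuclei grow more in
#       added_volume -0.14   0.099   135    relative terms; added volume
#        growth_rate  0.25   0.0038  135    itself is size-invariant: the
#  growth_duration_h -0.58   2.6e-13 135    adder signature)

csr <- combined_start_ratio(res$lineage_results$pairs$sisters, s)
csr$mean_ratio               # 0.974 -- sisters' combined starting volume
                             #          as a fraction of mother's ending
                             #          volume (configured: 0.959)
```

The numbers shown are the output of this exact script (135 full-interphase
trajectories from 384 tracks). The negative fold-change and duration
correlations with starting volume, the near-zero added-volume correlation,
and the CV ratio near √3 are the hallmarks of adder-like size control; the
combined-start ratio recovers the division retention the simulator was
given.

## Command line

```sh
inst/cli/nucgrowth simulate --out-dir out --config cfg.yaml --seed 1
inst/cli/nucgrowth qc       --features out/features.csv --out out/qc.csv
inst/cli/nucgrowth features --features out/qc.csv --out out/summaries.csv
inst/cli/nucgrowth report   --features out/features.csv \
                            --lineage out/lineage.csv --out-dir out/report
inst/cli/nucgrowth colony-area --stack stack.tiff --out-dir out
```

Config files are flat `key: value` lines with dotted prefixes
(`link.max_link_distance_um: 20`, `sim.n_founders: 40`).

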