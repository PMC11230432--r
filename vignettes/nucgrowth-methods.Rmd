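---
title: "Methods: models, parameters and design choices in nucgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in nucgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucgrowth)
```

`nucgrowth` analyses single-nucleus volume trajectories from multi-day
hiPSC colony timelapses sampled every 5 minutes. This vignette documents
the models it implements, the parameters that matter, what the synthetic
colony generator does and does not emulate, and the numerical choices made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The biological picture

After mitosis a nucleus re-forms its lamin shell, swells rapidly for about
40 minutes as nuclear import re-establishes the nucleoplasm, then grows
slowly for roughly 15 hours until the shell disassembles at the next
mitosis. A trajectory is the tracked record of one nucleus between those
two lamin-shell events; the *transition* separates rapid expansion from
slow growth, and the volumes at transition and breakdown define the
starting, ending and added volume of one generation.

## Tracking

Linking is a minimum-cost assignment between consecutive frames. With unit
mass per detection, the transportation formulation with virtual nodes
reduces to a square linear assignment: an `(n_a + n_b)` matrix with real
link costs in one block, `birth_death_cost` on the virtual diagonals, and
zero in the virtual–virtual block, solved exactly by a shortest
augmenting-path solver with dual potentials (`src/primitives.cpp`). The
test suite checks optimality against exhaustive enumeration of all
matchings on frames with up to 6 detections.

Cost and admissibility:

* `cost = dist/max_link_distance + volume_cost_weight * |dV|/mean(V)`,
  with `max_link_distance_um = 15` per 5-minute step (a knob: roughly 3x
  the per-frame motility of these cells) and unit volume weight.
* Links are inadmissible beyond the distance gate **or** beyond a relative
  volume difference `max_volume_frac = 0.4`. The volume gate is essential:
  at division the mother's volume roughly halves, and without it the
  gap-closing round happily bridges mitosis (cost ~0.9 < 2x the
  birth/death cost of 1.05), silently fusing mother and daughter tracks.
  Mitosis is deliberately never tracked through; daughters start fresh
  tracks and lineage links are annotations.
* `birth_death_cost = 1.05` sits just above the worst admissible real
  link, so real links are preferred whenever admissible.

Gap closing re-runs the same optimisation between track ends and track
starts up to 3 frames later, excluding detections at the field-of-view
edge (their tracks likely ended by leaving the image). Skipped frames
remain in the merged track as missing-value records.

## Trajectory quality control

Three automated filters: FOV-edge records are excluded (but retained in
the table), tracks with fewer than 5 observed frames are dropped, and a
timepoint is an outlier when its volume deviates more than 15% from the
median of a centred 15-frame window. The window is centred because the
stated padding (head: first value; tail: median of the last three values)
only makes sense for a centred window: the head padding prevents the
genuine rapid expansion from flagging itself, while the tail padding lets
the mitotic volume jump at the very end be caught. The long-duration
outlier subpopulation (manually curated in the original study) is exposed
as an optional mean + 3 SD rule, off by default.

A *full-interphase* trajectory has formation, breakdown, a valid
transition, spans at least 120 frames (10 h) and has non-negative overall
growth.

## Start of growth (transition detection)

The first 40 frames after formation are min-max normalized in time and
volume, linearly interpolated across missing values, and resampled at 200
points uniformly spaced in cumulative arc length — this concentrates
samples around the bend. The curve is fit to a hyperbola in implicit
two-line form

$$(y - m_1 x - c_1)(y - m_2 x - c_2) = k,\qquad k > 0,$$

chosen because its asymptotes and centre (their intersection) are explicit
model parameters. The fit minimises the sum of squared implicit residuals
by BFGS with an analytic gradient, initialised from the exhaustive
two-segment piecewise-linear fit, with `k` parameterised on the log scale
to stay positive. The transition abscissa is the data x whose hyperbola
point lies nearest the centre.

One refinement was needed beyond the plain hyperbola: the growth segment
is a power law with exponent typically above 1, so it is concave-up and
the fitted second asymptote is a chord; this biases the centre 2–5 frames
late. A local two-line refinement (line through the frames at or before
the estimate; line through the 12 frames after it; move to their
intersection; iterate 3 times) removes the bias — mean absolute recovery
error on simulated tracks drops from ~3 frames to ~0.5. The estimate is
finally snapped to the nearest frame with a valid record within 2 frames.
Validity requires asymptote slopes separated by at least 0.15 (normalized
units) — an exactly linear trajectory fails — and a residual RMSE below
0.05.

## Growth shape and rates

`fit_power_law()` fits $V(t) = V_{start} + r t^\alpha$ (t in hours since
transition) by profiling: for fixed $\alpha$ the linear parameters solve
an ordinary regression on $t^\alpha$, and $\alpha$ is optimised on
[0.2, 3]. This is numerically robust (no multi-parameter nonlinear
optimiser), exactly reduces to linear regression when $\alpha$ is pinned
at 1, and recovers a noise-free exponent to better than 1e-3. A fit is
flagged invalid when the fitted rate is numerically zero (flat volume:
$\alpha$ unidentifiable). Residuals are treated as homoscedastic on raw
volumes — fit error in real data exceeds what measurement noise explains,
so no finer noise model is warranted.

The transient growth rate is the centred difference over a 4-hour window
(48 frames; the half-window rounds to the nearest frame), missing wherever
an endpoint is missing, the window leaves the track, or the timepoint is
within 2 h of formation or 30 min of breakdown (expansion and pre-mitotic
dynamics are excluded by construction). Early/late means are taken over
the first 30% and last 25% of valid windows.

## Colony context

Neighbours are Delaunay-adjacent centroids (equivalently, shared Voronoi
ridges), computed by an in-package Bowyer–Watson triangulation (no
pre-installed R Delaunay library) that the tests verify against a
brute-force empty-circumcircle oracle. Local density is
`1/mean(neighbour distance)^2` and the approximate cell radius is half the
mean neighbour distance, so `density = 1/(2 radius)^2` exactly.

The colony boundary is defined as nodes with unbounded Voronoi regions —
convex-hull vertices — *plus* nuclei within half the median Delaunay edge
length of the hull polygon. The extension matters: a boundary nucleus
perturbed a micron inward of the hull is still biologically on the colony
edge, and without it the edge ring of a colony is assigned depth 2 almost
everywhere. Depth is then breadth-first distance from the boundary
(boundary depth 1), after pruning Delaunay edges longer than 3x the median
(they jump across ragged bays), and the normalized distance from colony
centre is $d_N = (d_{max} - d)/(d_{max} - d_{min})$, with the all-boundary
degenerate case defined as $d_N \equiv 1$.

Colonies are aligned in developmental time by the integer lag minimising
the mean squared difference of their mean-height series over the overlap
(raw means, minimum overlap 60 frames, ties to the smallest |lag|). The
hexagonal-prism model converts nuclear volume to cell volume with NC ratio
0.28 and predicts the in-plane radius `s*sqrt(3)/2` from `Volume = 3ash`;
the comparison to measured radii uses a Gaussian-weighted moving average
over height with a 0.5 μm bandwidth. Neighbourhood-averaged transient
rates use a 90 μm radius and exclude the focal nucleus, so the Fig-style
correlation of own rate with neighbourhood rate cannot be self-inflated.

## Population and lineage statistics

CVs use the sample (n−1) standard deviation. Bootstrap confidence
intervals resample observation pairs 500 times and take the 5th/95th
percentiles (a 90% interpercentile band); degenerate resamples are
dropped. Significance of a difference between two correlations is
non-overlap of their 90% CIs — no additional test. On null data this
rule has an intrinsic per-comparison false-positive rate of a few percent,
which the tests measure explicitly rather than pretending it is zero.

Sister correlations are computed on the order-symmetrized set (each pair
contributes both orderings) so they do not depend on arbitrary member
order; bootstrap resampling operates on pairs, not on the doubled rows.
Control pairs use strict inequality gates (10 min / 60 μm / 80 μm³ for
control sisters; 60 min / 60 μm / 60 μm³-of-half-the-ending-volume for
control mother–daughter pairs), and each nucleus appears in at most one
control pair, matched greedily by smallest combined normalized mismatch —
a conservative choice where the original procedure is unspecified.

The steady-state adder map $V' = (V + \Delta V)/2$ with iid added volumes
has $\mathrm{Var}(V_{start}) = \sigma^2_{\Delta V}/3$, hence
$CV(\Delta V)/CV(V_{end}) = \sqrt{3} \approx 1.73$ and mean fold-change 2;
`simulate_adder_lineage()` and `simulate_adder_population()` realise this
with the printed population moments (517.9 ± 54.9 μm³ starting volume,
added-volume CV 0.177, both truncated at zero).

## The synthetic colony generator

`simulate_colony()` is the stated world all pipeline stages are tested
against. Per track: a linear expansion ramp from 72% of the starting
volume over a duration drawn from N(38, 10) min; a power-law growth
segment with exponent drawn from N(1.15, 0.2) truncated to [0.5, 2],
whose total added volume is drawn independently of starting volume
(mean 517.9 μm³, CV 0.177 — the adder); growth duration
N(14.9, 1.9) h decomposed into a size-compensation term (slope derived
from the target duration–size correlation of −0.55), a heritable latent,
and individual noise; division retains N(0.959, 0.042) of the ending
volume (truncated to (0.5, 1.2): truncating at 1 would bias the realised
mean retention to ~0.947), split with daughter fraction N(0.5, 0.015);
multiplicative measurement noise of 0.64% per frame. Founders stagger
their formation over 15 h so the population is asynchronous.

Choices that deserve justification:

* **Expansion shape.** A linear ramp, not a saturating exponential. The
  paper-scale quantities constrain the expansion's duration, not its
  shape; a ramp keeps the expansion steep right up to the hand-over, which
  is what produces the abrupt slowdown visible in real trajectories. A
  saturating shape whose slope decays to zero before the transition makes
  the transition genuinely ill-defined — no estimator can then recover it
  to ±2 frames, ours included.
* **Neighbourhood coupling.** Instantaneous growth rates are multiplied by
  a shared Gaussian-smoothed random field (length scale 90 μm, time scale
  4 h, amplitude 0.3), then renormalised per track so the trajectory still
  adds exactly its drawn adder increment. Coupling therefore redistributes
  growth within a generation without touching the adder bookkeeping;
  without the renormalisation the realised added-volume CV inflates to
  ~0.24 and the CV-ratio property the generator is supposed to exhibit is
  destroyed. The field is descriptive — the study demonstrates the
  correlation, not a generative law.
* **Heritable duration.** Duration–size compensation alone cannot make
  growth duration *inherited* in the matched-control sense, because
  control pairs are volume-matched too and inherit the compensation
  equally. Each division therefore draws one duration latent (SD 45 min,
  mother-to-daughter correlation 0.5) shared by both sisters. With it,
  sister duration correlations run ~0.4–0.5 against control correlations
  ~0.1–0.2, reproducing the inherited-duration finding; without it the
  panel cannot distinguish the groups at any sample size.
* **Heights** follow a radial gradient whose slope drifts linearly from
  negative (edge-high) to positive over the movie, producing the
  qualitative sign reversal of developing colonies. This is descriptive
  only: heights are *not* generated from the packing model, so the
  hex-prism consistency test builds its own packed-lattice fixture rather
  than using colony output.
* **What the generator does not emulate:** segmentation errors beyond
  multiplicative volume noise, apoptosis, colony fusion or migration out
  of the field of view, z-motion, or any mechanistic nuclear-envelope
  biophysics. A green pipeline test therefore establishes correctness of
  the analysis on data with the stated statistical structure, not
  robustness to every imaging pathology.

The bright-field phantom is a textured disk whose in-plane texture
amplitude is minimal at the focal plane and peaks above and below it — the
through-focus contrast signature of a phase object. The texture is
spatially correlated (σ = 2 px): Sobel's smoothing taps annihilate
pixel-iid noise, and a phantom that a correct implementation cannot
segment would test nothing. Amplitude 0.45 against a 0.003-noise
background gives recovery within ~3% across radii 30–100 μm.

## Numerical choices and degenerate inputs

* Rectangular assignment uses a large finite cost (1e6) for inadmissible
  links; infeasibility is detected, not silently absorbed.
* The Bowyer–Watson triangulation normalises coordinates to the unit box
  and places the super-triangle at distance 1e5 — close enough for double
  precision, far enough that no realistic circumcircle contains it (the
  earlier 20x margin measurably dropped hull-adjacent edges).
* `align_colony_time` breaks MSE ties toward the smallest |lag|, then the
  smaller lag, so constant series return 0 deterministically.
* Collinear point sets and sub-3-point frames raise degenerate-geometry
  errors; isolated nodes yield missing density; zero-variance inputs yield
  missing correlations rather than NaN propagation.
* All randomised procedures consume the caller's RNG state (R convention);
  `sim_config(seed=)` pins the simulator, and the pipeline seeds bootstrap
  stages from `pipeline_config(seed=)`.

## Known limitations

* Tracking assumes nearly-planar colonies; the 3D centroid distance is
  used but no z-specific gating exists.
* The transition detector requires ~8 usable frames and a genuine slope
  change; trajectories already in slow growth at movie start are rejected
  rather than extrapolated.
* Control-pair matching is at-most-once greedy; a globally optimal
  matching could yield slightly more pairs.
* The colony-area module implements one classical recipe; it is validated
  on phantoms, not on real bright-field stacks.
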