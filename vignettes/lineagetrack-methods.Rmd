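---
title: "lineagetrack: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lineagetrack: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science behind its
pipeline: the tracking and linking model, the fate-classification rules,
the bioparameter estimators, the synthetic-movie generator that stands in
for experimental data, and the reasoning behind every numerical default.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The tracking model

Frames arrive as label masks (from the built-in segmenter, from oracle
masks, or from an external backend). Between consecutive frames the
tracker minimizes **contour variation**, scored as `1 − IoU` of the two
pixel supports. With a 30-minute frame interval and adherent epithelial
cells whose typical displacement per frame is far below a cell diameter,
overlap is an almost sufficient statistic for identity; no motion model
is used.

The per-frame-pair assignment is the **optimal one-to-one bipartite
matching** restricted to pairs with cost below a gate (default `gate =
0.9`, i.e. any pair with IoU > 0.1 is linkable). Optimality is
cardinality-first: the matching maximizes the number of linked objects
and, among those, minimizes total cost. We solve it with a maximum-weight
bipartite matching (igraph) with weight `K − cost` for a large `K`, plus
an infinitesimal preference for smaller labels so ties break
deterministically. Greedy matching would fail exactly in the situation
that matters here — clusters of sisters after division — which is why the
crossing-objects case is part of the unit tests.

There is **no gap closing**: a segmentation dropout ends a track (fate
`LOST`) and restarts another (`SPONTANEOUS`). This mirrors the downstream
treatment of spontaneous appearances as a known artifact class that is
excluded from biological analyses rather than patched over.

## 2. Linking: divisions, entries, spontaneous appearances

An object appearing at frame *t* mid-movie is explained by exactly one of
three mechanisms. Its contour is compared with the previous frame: the
candidate mother is the frame-(t−1) object holding the largest fraction
of the new contour, and if that fraction reaches `tau_div = 0.5` the
appearance is a **division**. At this frame rate daughters still lie
within their mother's footprint, so 0.5 ("at least half of the new cell
was the mother") is a natural threshold; it is configurable. Otherwise an
appearance whose bounding box lies within `border_margin_px = 2` of the
frame edge is a **boundary entry**, and anything else is **spontaneous**.

Division bookkeeping is strictly binary. The daughters' birth frame is
the first frame both are observed; the mother ends the frame before with
fate `DIVIDED`. When frame matching carried the mother's identity onto
one of the daughters, that continuation is split off as a new track with
origin `DAUGHTER`, so the mother's lifetime statistics are not
contaminated by a daughter's. When three or more objects claim one mother
at the same frame, the two best claims are kept (the continuation, if it
exists, is always one of them) and the rest are demoted to spontaneous,
with a warning. A lone claimant over a mother that vanished the frame
before cannot form a binary division; consistent with the no-gap-closing
rule, the mother becomes `LOST` and the claimant `SPONTANEOUS`.

Lineage trees are the weakly connected components of the mother–daughter
graph. A component rooted in a spontaneous track is excluded *as a
whole*: a spontaneous track can itself divide, and its descendants have
no legitimate founder. (The obvious alternative — excluding only the
spontaneous track and re-rooting its daughters — would fabricate
founders, which biases the tree-category counts.)

## 3. Fate classification and filtering

Trees are categorized by the founder's observed behaviour relative to the
**normal-cycle window of 10–40 h**:

* founder divides with first-division time ≤ 40 h → **proliferative
  tree**; all members are `PROLIFERATIVE`;
* founder divides later than 40 h → **transiently arrested tree**; the
  founder is `ITA`, all progeny are `RPTA`;
* founder never divides and is observed to the end of the window →
  `LTA` (long-term arrested, a single-cell "tree").

Founders present at frame 0 have unknown birth, so their time to first
division is a lower bound; we classify on it anyway (this is conservative
for arrest calls and is the only interpretation that needs no unobserved
quantity). A founder that disappears before the movie ends without
dividing is `UNCLASSIFIED` and excluded — we make the category explicit
rather than silently dropping such roots, so that category partitions
remain testable. Proliferative founders and their progeny are *not* split
into subcategories; their measured behaviour does not differ enough to
warrant it, and a single class keeps counts interpretable.

Filtering happens before any population statistic: spontaneous tracks;
debris (track median area below `debris_min_um2 = 300` µm², far below any
real cell at this magnification); and complete cycles shorter than 10 h,
which at this frame rate are reconstruction artifacts — the cell and its
whole subtree are removed, and every removal is logged with a reason.

## 4. Bioparameters

**Growth.** N(t) = N₀·e^{rt} is fitted by least squares on log counts —
deterministic, adequate for counts ≥ 1, and the doubling time follows as
T_d = ln 2 / r exactly (an invariant asserted in the tests). A negative
rate is reported as decay with a negative T_d rather than an error.

**Diffusion.** For each cell the per-step instantaneous estimate
dᵢ = (Δxᵢ² + Δyᵢ²)/Δt is summarized by its **median** over the
trajectory, which suppresses the abrupt displacements of mitosis and rare
tracking glitches. For an ideal 2-D Brownian walk with true coefficient
D the steps are exponential-like with mean 4D, so the median converges to
4·ln 2·D ≈ 2.77·D. The estimator is therefore a robust *comparative*
motility index, not an unbiased estimate of D; the test suite pins the
4·ln 2·D relation by simulation, and the simulator's motility presets are
chosen on the same scale so that reported medians land in realistic
ranges (see §6). Mitotic frames are deliberately not excluded — the
median is the outlier guard.

**PTE.** The probability to exceed, PTE(x) = P(X ≥ x), is the empirical
complementary CDF: 1 at the sample minimum, decreasing to 1/n at the
maximum. The median is read off where the curve crosses 0.5. To make that
crossing well-defined for small samples we interpolate through mid-point
(Hazen) plotting positions, which makes the PTE median equal the ordinary
sample median for odd n and the midpoint of the central pair for even n.

**Bootstrap error of the median.** Two stages: a pool of 10⁵ values drawn
with replacement from the sample, then 10³ subsamples of 100 from that
pool; the standard deviation of the 10³ subsample medians is the reported
error. Note the quirk, preserved deliberately: the error reflects the
fixed resample size (100), not the real sample size, so errors are
comparable across conditions of different n but are not standard errors
of the observed median. The 1/√(resample size) scaling is pinned by a
test against the asymptotic formula 1/(2·φ(0)·√m) for normal samples.

## 5. The synthetic-movie generator

The generator emulates the structure of multi-day GFP-cytoplasm movies of
an epithelial line after irradiation, with exact ground truth (masks,
cell table, trees):

* **Geometry.** Cells are ellipses (aspect 0.7–1.3, orientation and
  aspect drifting smoothly). Rasterization assigns contested pixels to
  the cell with the smaller normalized elliptical distance, so masks
  never overlap and are deterministic.
* **Cycles.** Cyclers draw from a Gaussian centred at 23 h (sd 9 h)
  truncated to the 10–40 h normal-cycle window. Transiently arrested
  founders draw their delayed first cycle uniformly from 45–85 h — the
  experimental statement is only "longer than 40 h", so a uniform
  stand-in is used, with the upper end inside the 96 h window so that the
  delayed division is actually observable and truth categories remain
  recoverable from observation. Progeny of arrested founders cycle
  normally. Long-term arrested cells never divide.
* **Division geometry.** The mother splits along her minor axis; each
  daughter has half her area and is placed at half the mother's
  semi-minor axis on either side of her centre, i.e. both daughters lie
  inside the mother's former footprint — which is what makes
  division-vs-appearance disambiguation by overlap possible at all. The
  sisters then separate over a few frames through a capped
  contact-relaxation push (cells relax toward just-touching at their
  directional ellipse radii plus one pixel). An early design that placed
  daughters edge-to-edge outside the footprint broke the τ = 0.5 overlap
  rule in crowded scenes and was replaced.
* **Motion.** Reflected 2-D Brownian steps with per-coordinate sd
  √(2·D·Δt); per-category D (µm²/h): proliferative 0.15, RPTA 0.20, ITA
  0.02, LTA 0.01. These are *true* coefficients; through the 2.77×
  median factor they land the reported medians in the ranges typical of
  motile vs arrested epithelial cells (≈0.4 / 0.55 / 0.055 / 0.03
  µm²/h). Optionally borders can be absorbing with boundary entries, to
  exercise the `LEFT_FIELD` / `ENTERED_BOUNDARY` fates.
* **Area dynamics** (µm², base 4500): cyclers recover from half their
  mother's final area to base within ~5 h and swell 10% linearly over the
  last 20% of their cycle (so division conserves area by construction);
  arrested founders swell to 3× base over 40 h and plateau; long-term
  arrested cells grow linearly at 10%/h of base, reaching ~10× base after
  4 days — the hypertrophy that makes them the largest, slowest class.
* **Dose.** Dose acts only through the tree-category mixture (and the
  presets above). Anchor mixtures per integer dose follow the published
  founder-count proportions (proliferative-dominated at 0–1 Gy, arrest-
  dominated at 4–5 Gy), interpolated for fractional doses. No mechanistic
  dose–response is modelled.
* **Rendering.** Background + linear illumination gradient + per-cell
  signal with brightness variation and **radial edge shading** (cytoplasm
  is optically thinner near the membrane, so touching cells show a dim
  seam), plus Gaussian read noise and signal-dependent shot noise, on a
  16-bit scale. The seam is not a convenience: without it, images of
  confluent colonies contain no information separating touching cells,
  and no non-learned segmenter could recover them.
* **Confluence guard.** Configurations whose expected end-of-movie
  coverage exceeds ~90% of the field are rejected up front
  ("over-confluent configuration"), since cells could not be placed
  without overlap.
* **Determinism.** One seeded RNG stream drives all sampling in a fixed
  iteration order; identical config + seed gives bit-identical movies,
  masks and tables. The caller's RNG state is restored afterwards.

`perturb_masks()` degrades the exact masks independently of any
segmenter: per object and frame, an integer centroid jitter (sd 2 px ×
noise), a one-pixel boundary dilation/erosion (probability = noise), and
a dropout (probability 0.01 × noise; the parameter can be raised to 1 to
produce the empty-mask limiting case). At the benchmark level 0.15 this
leaves per-object IoUs high but not perfect and produces a realistic
handful of broken tracks per movie.

**What the synthetic benchmark does not show.** Real movies contain
debris, focus drift, intensity bleaching, apoptotic fragmentation,
genuinely non-elliptical and non-Brownian cells, and segmentation errors
correlated in time and space; the perturbation model is independent
across object-frames. Passing the benchmark therefore demonstrates the
correctness and robustness of the tracking/linking/scoring machinery
under controlled degradation, not the field performance of the built-in
segmenter on experimental data — on real data one would plug a trained
segmentation model into the `external` backend seam.

## 6. The built-in segmenter

Gaussian smoothing (σ = 1 px), Otsu threshold (a fixed threshold can be
supplied), hole filling, then a watershed on the **sum of the distance
transform and the weighted smoothed intensity** (weight 4): shape necks
*and* dim seams between touching cells both deepen the saddles, so the
watershed separates sisters that a pure distance transform cannot.
Watershed tolerance 0.5 and a minimum object area of 30 px were
calibrated once on a seeded rendered fixture; they trade a small number
of false splits of large arrested cells against merges in colonies.
Per-dose segmentation profiles are represented as parameter sets, not
learned models — the architecture seam for a trained backend is
`segment_movie(..., backend = "external")`.

## 7. Tracking-quality metrics

Detection matching per frame is the optimal assignment among pairs with
IoU ≥ 0.5 (HOTA convention). **DetA** = TP/(TP+FN+FP) pooled over frames.
**AssA** is the HOTA association score: for every matched detection the
intersection of its ground-truth and predicted tracks over the union of
both, averaged over matched detections. **Lineage assignment** maps each
predicted track to a ground-truth track by majority vote over matched
detections, each predicted tree to the ground-truth tree with most
corresponded cells, and reports the percentage of corresponded cells
whose predicted tree maps to their true tree — spontaneous tracks
excluded first. **Division scores** match predicted to true divisions
when mothers correspond and frames differ by ≤ 2. **Lifetime agreement**
is the percentage of true complete cycles whose corresponding predicted
complete cycle differs by ≤ 2 frames (1 h); an absolute tolerance was
chosen because the comparison is frame-resolved and the relevant error
mode (division detected a frame early/late) is additive, not relative.

## 8. Problem sizes and the standing benchmark

The package's standing validation experiment (`run_benchmark()`, also run
by `scripts/acceptance.R` and the acceptance tests) uses ten seeded
movies of 192 frames at 0.5 h on a 256 px / 1330 µm field with 5–10
founders at the 2 Gy category mixture — large enough for every fate
category and several division generations per movie, small enough that
the whole experiment runs in minutes on one CPU. Tracking quality is
scored on masks perturbed at noise 0.15; detection accuracy of the
built-in segmenter is scored on the rendered frames of the same movies.
Pooled percentages are weighted by their per-movie sample sizes
(corresponded cells, complete cycles, matched detections), identically to
pooling the underlying counts.

## 9. Known limitations

* Cell fusion, apoptosis as a distinct fate, and multi-hypothesis
  tracking are out of scope; a dropout always costs a track.
* The overlap gate assumes displacements small relative to cell size per
  frame; fast cells or slow frame rates would need a motion model.
* The simulator's arrest-delay distribution (uniform 45–85 h) is a
  stand-in; no experimental distribution is available beyond the 40 h
  threshold.
* The diffusion estimator is a scaled median, not an unbiased D; compare
  values only to other values produced by the same estimator.
* Initial-cell cycles are right-censored at frame 0 and classified on
  the lower bound, which can only under-call transient arrest.
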