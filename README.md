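# lineagetrack

Single-cell tracking, lineage reconstruction and fate analysis for
time-lapse fluorescence videomicroscopy of adherent cells — with a
synthetic-movie simulator and tracking-quality metrics, so the whole
pipeline is testable end to end without any experimental data.

## The problem

After a perturbation such as X-ray irradiation, cells in one dish take
divergent paths: many keep cycling, some arrest for a long interval and
then resume, and some exit the cell cycle for good. Population-level
readouts (confluence, bulk growth curves) average these fates away. The
package reconstructs what every cell and its descendants did over a
multi-day movie:

1. **Pre-processing** — rolling-ball background subtraction and percentile
   contrast rescaling (`preprocess_frame()`).
2. **Segmentation** — per-frame label masks via Gaussian smoothing, Otsu
   threshold and a watershed on distance-transform + intensity
   (`segment_frame()`); the backend is pluggable (`segment_movie()`), so
   oracle masks or an external learned segmenter can be swapped in.
3. **Tracking** — identities are propagated by minimizing contour
   variation between consecutive frames, cost `1 − IoU`, with an optimal
   one-to-one bipartite assignment and a gate (`track_movie()`).
4. **Linking** — each mid-movie appearance is resolved into a division
   (mother = previous-frame object holding ≥ τ of the new contour), a
   boundary entry, or a spontaneous appearance; divisions are strictly
   binary and lineage trees are the components of the mother–daughter
   graph (`link_tracks()`, `build_trees()`).

Trees are then classified by the founder's behaviour (`classify_cells()`):
**proliferative** (first cycle ≤ 40 h), **transiently arrested** (first
cycle > 40 h; the founder is *ITA*, its progeny *RPTA*), and **long-term
arrested** (*LTA*: no division within the 4-day window). Filtering removes
debris, spontaneous tracks, and complete cycles shorter than 10 h.

Per cell and per population the package computes (`R/bioparams.R`):

- exponential growth N(t) = N₀·e^{rt} with doubling time T_d = ln 2 / r;
- an effective diffusion coefficient D = median over the trajectory of the
  per-step (Δx² + Δy²)/Δt (the median suppresses mitotic jumps);
- surface areas from pixel counts scaled by the field calibration
  (default 1330 µm field of view);
- probability-to-exceed curves PTE(x) = P(X ≥ x) whose 0.5 crossing is the
  median, with a two-stage Monte-Carlo bootstrap error on the median
  (10³ resamples of 100 from a 10⁵ pool).

Because no public movies accompany this problem class, `simulate_movie()`
generates GFP-cytoplasm-like movies with exact ground truth: elliptical
cells, reflected Brownian motion, category-dependent cycle times
(truncated Gaussian 23 ± 9 h on 10–40 h for cyclers, delayed first
division for transient arrest, none for LTA), category-dependent area
dynamics and motility, and dose-dependent category mixtures.
`evaluate_tracking()` scores any reconstruction against that truth with
HOTA-style detection and association accuracy, lineage-assignment
accuracy, division precision/recall, and cycle-duration agreement.

## Worked example

```r
library(lineagetrack)

cfg <- sim_config(image_size_px = 256, duration_h = 95.5,
                  n_initial_cells = 8, dose_Gy = 2, seed = 5)
sim <- simulate_movie(cfg, render = FALSE)

upp   <- cfg$field_um / cfg$image_size_px
masks <- perturb_masks(sim$truth, noise_level = 0.15, seed = 1005)
tr    <- track_movie(masks, um_per_px = upp, dt_h = cfg$dt_h)
tr    <- link_tracks(tr, masks)
tr    <- build_trees(tr)$tracks
evaluate_tracking(sim$truth, tr, masks)
```

```
tracking metrics (IoU >= 0.50):
  DetA                0.999
  AssA                0.983
  lineage assignment  100.0%
  division P / R      1.000 / 1.000
  lifetime agreement  100.0%
```

So on this movie the tracker found 99.9% of the perturbed objects, kept
identities at association accuracy 0.98, detected every division, put
every corresponded cell into the right lineage tree, and reconstructed
every comparable cell-cycle duration within the 2-frame (1 h) tolerance. Classification and bioparameters then
run on the same object:

```r
tr  <- classify_cells(tr)
fl  <- filter_cells(tr)
head(counts_over_time(fl$tracks))
cell_diffusion(fl$tracks)
```

A command-line front end wrapping the same steps (subcommands `simulate`,
`track`, `classify`, `analyze`, `evaluate`) is installed at
`inst/cli/lineagetrack.R`.

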