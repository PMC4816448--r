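---
title: "Reconstructing missing marker trajectories from marker inter-correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing missing marker trajectories from marker inter-correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerfill)
```

## The model

Optical motion capture tracks `m` reflective markers at `n` discrete time
frames; `markerfill` stores a trial as the `n × 3m` measurement matrix
**M** (X, Y, Z columns per marker, millimetres). Human movement is highly
coordinated, so the rows of **M** concentrate near a low-dimensional
affine subspace: a few principal components explain almost all of the
variance. A marker hidden from the cameras for a stretch of frames can
therefore be predicted from the markers that remain visible, provided the
relationship between them is learned from the frames where everything was
visible.

The engine (`reconstruct_eq1()`) implements this as a pair of principal
component bases and a transition between them:

1. **Training set.** The complete frames of **M** form **N**. A copy
   **N**~zeros~ has the columns of every corrupted marker replaced by
   zeros.
2. **Weighting.** Each marker's three columns are scaled by a weight.
   A marker `j` that is not being reconstructed gets
   `w_j = exp(-dbar_j^2 / (2 sigma^2))`, with `dbar_j` the time-averaged
   Euclidean distance between `j` and the target over their shared frames
   (`mean_marker_distance()`); when several markers are reconstructed at
   once, the largest weight over the targets is used. The target's own
   columns get the small constant `w_mm`. Weighting focuses the
   decomposition on the markers that actually carry information about the
   gap — in real marker sets, the neighbours on the same and adjacent
   body segments.
3. **Bases.** Both weighted, column-centered matrices are decomposed by
   SVD (`fit_basis()`). The number of retained components is the smallest
   `k` at which the cumulative sum of *normalized singular values* (each
   value divided by their total — values, not squared variances) reaches
   `theta_lambda`.
4. **Transition and reconstruction.** A matrix **T** maps the truncated
   scores of the zeroed representation onto those of the full one
   (`transition_matrix()`). Every row of the centered, weighted,
   zero-filled **M**~zeros~ is projected onto the zeroed basis, passed
   through **T**, and expanded through the transpose of the truncated
   full basis (the pseudoinverse of an orthonormal column block). After
   dividing the weights back out and restoring the column means, the
   predicted coordinates replace the missing samples — and only those;
   observed samples are bit-identical before and after.

Because centering is carried out before zero filling, a zero entry means
"at the training mean", and the whole procedure is equivariant under
rigid translation of the lab frame and under renumbering of the markers.

## Strategies for gaps in several markers

**R1** (`reconstruct_r1()`) fills everything in a single pass: all
corrupted columns are zeroed together and every complete marker's weight
is its best weight over all targets. Its two structural weaknesses: one
weight vector must serve all gaps at once, and training frames are only
those complete in *every* marker.

**R2** (`reconstruct_r2()`) fills each corrupted marker separately from
the original corrupted data. For target `i`, another corrupted marker `h`
is either *included* — then `h`'s own gap frames are dropped from
training — or *omitted* entirely. The decision (`select_neighbors_r2()`)
is distance based: `h` is omitted when `dbar(i,h) > theta_d * D_i`, where
`D_i` is the mean of `i`'s average distances to all other markers, and
omitted unconditionally when `h`'s gaps overlap `i`'s in time (such a
neighbour can never contribute during the frames that matter). Gap-free
markers are always kept. R2 therefore trades markers for frames: each
target trains on every frame that is complete over its *included*
markers — a strict superset of R1's rows whenever gaps are disjoint.

Two deliberate choices here. First, R2 never feeds one marker's
reconstruction into another's: every marker is predicted from the
original data, which removes any dependence on processing order (a
property the test suite asserts). Second, "overlap" means a single shared
gap frame — the strictest reading. A marker whose reduced dataset ends up
without support (all neighbours omitted, or too few complete frames) is
reported unfilled rather than aborting the run.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `w_mm` | 0.02 | – | weight of the target's own columns; must be > 0 |
| `sigma` | 200 | mm | length scale of the Gaussian neighbour weighting |
| `theta_lambda` | 0.99 | – | cumulative singular-value threshold for truncation |
| `theta_d` | 0.5 | – | relative distance cutoff for R2's omission rule |

`w_mm = 0` is rejected outright: the two bases would coincide, the
transition would be the identity, and the reconstruction would return
zeros for the gap columns. `sigma = 200` mm concentrates the analysis on
markers within roughly one body segment; very small values (≈ 100 mm)
can leave a target with effectively no informative neighbour and degrade
results sharply, while large values flatten the weighting. `theta_d`
controls R2's frames-versus-markers trade-off: small values favour
keeping frames (good for short trials), large values favour keeping
markers.

### The transition-matrix convention

The algebraic link **T** between the two truncated score spaces is not
uniquely determined by the construction above, and the package exposes
two conventions through `recon_params(transition = )`:

* `"scores"` (default): **T** is the least-squares solution mapping the
  zeroed scores of the training frames onto the full scores. This is the
  training-error minimizer; in particular it makes reconstruction *exact*
  (to numerical precision) whenever the data lie in the span of the
  complete-frame components, which is the basis of the package's
  exact-recovery tests and of its agreement with a direct least-squares
  subspace completion.
* `"basis"`: **T** is the inner-product matrix of the two truncated
  bases. This convention couples the result much more strongly to
  `w_mm` — with `w_mm` near 1 the full basis rotates away from the
  zeroed one and the error grows severalfold, so a weight well below 1
  becomes genuinely important, which is the behaviour classically
  reported for this family of algorithms. The price is the loss of the
  exactness property: even noiseless low-rank data is no longer
  recovered to machine precision.

The two properties are mutually exclusive — a training-optimal map
cannot simultaneously be badly suboptimal for large `w_mm` — so a single
default cannot exhibit both. The default is `"scores"`, preferring
accuracy and the exactness guarantee; under it the dependence of the
error on `w_mm` keeps the expected *direction* (larger at `w_mm = 1`
than at 0.02) but is small in magnitude on the synthetic data, and the
test suite records exactly that.

## The synthetic gait generator

`generate_gait()` exists so the whole pipeline is testable without any
recordings. It emulates the structure the reconstruction relies on, and
its design choices matter more than usual, because two of the paper-level
phenomena — the usefulness of distance weighting and R2's advantage over
R1 — only appear if the synthetic data shares specific properties of
real marker sets:

* **Low-rank shared motion.** `latent_rank` (default 8) sinusoids at
  harmonics of the stride frequency, plus one slow drift component, are
  mixed onto the marker coordinates and scaled to `amplitude_scale`
  (300 mm RMS). With noise and soft tissue switched off the generated
  matrix has numerical rank `latent_rank + 1` (the +1 is the constant
  offset), which the tests assert.
* **Markers clustered on a connected chain.** Markers are placed three
  per segment (`segment_spread` = 70 mm) on segments that form a random
  walk with 300 mm steps inside a standing-person volume, and the mixing
  coefficients are a smooth Gaussian random field (length 600 mm) over
  segment positions. Nearby markers therefore move almost alike and
  distances decay along the chain — exactly what makes Gaussian
  weighting informative and the omission of distal corrupted markers
  cheap. With markers scattered uniformly in a box, proximity carries no
  kinematic meaning and R2's neighbour selection actively hurts.
* **Locally coherent soft tissue.** Each segment carries a shared
  smooth artifact (4 mm), each marker a smaller private one (1.5 mm),
  plus 0.5 mm white noise. Skin motion is locally coherent in reality;
  modelling it as fully independent per marker would deny R2's
  concentrated local weighting the ability to predict it and again
  invert the R1/R2 ordering.
* **Regime switching.** A `transition_frame` switches the stride
  frequency (×1.3) and perturbs the mixing fields (relative size 0.2),
  emulating a walk-to-run transition whose correlation structure differs
  between halves (asserted as a positive principal angle between the
  two complete-frame subspaces).

Three presets fix the trial geometries used in the experiments:
`walkl` (4300 frames, 240 Hz, 37 markers), `cp` (600 frames, 200 Hz, 35
markers, larger soft tissue), `walkrun` (400 frames, 120 Hz, transition
at frame 200). What the generator does *not* model: musculoskeletal
constraints, non-stationary amplitude drift, marker swaps, and genuinely
non-cyclic movements. Passing tests on this data demonstrate the
algebra and the qualitative orderings, not performance on any particular
laboratory's recordings.

`corrupt_with_gaps()` applies the randomized corruption protocol: a
uniform number of gaps, uniform marker (with replacement), uniform start
frame and uniform duration; overlapping gaps on one marker merge. A
configuration leaving fewer than 5% of frames complete is redrawn, so
the engine always has a training set.

## Evaluation harness

`score_reconstruction()` reports the mean Euclidean distance between
reconstruction and truth pooled over all missing marker-frames (plus
per-axis MAE and per-marker means). Pooling, rather than averaging
per-marker means, weights every missing sample equally.
`replicate_experiment()` runs 50 seeded corruptions by default and
returns the per-replicate errors and their median; replicate seeds are
drawn once from the master seed, so results are reproducible bit for
bit and different methods scored under the same master seed see the
same corruptions. `sensitivity_sweep()` performs the one-at-a-time
parameter sweeps on the standard grids (15 logarithmic steps over
1e-5–1 for `w_mm`; 15 linear steps over 100–1500 mm for `sigma` and
0.86–1 for `theta_lambda`; 11 linear steps over 0–2 for `theta_d`),
centering each corrupted copy's error curve by its own mean before
averaging, which isolates the parameter effect from the difficulty of
the individual corruption.

## Numerical conventions and degenerate inputs

* Centering uses the complete-frame column means; the same means are
  restored after reconstruction. Zero filling happens after centering
  and weighting.
* `(PC)^-1` under truncation is the transpose of the truncated
  orthonormal block.
* Truncation indices are chosen independently for the two bases with
  the same `theta_lambda`.
* The least-squares transition is solved through the SVD pseudoinverse;
  a rank-deficient score matrix produces a condition-number warning but
  still yields the minimum-norm solution.
* At least `max(10, min_complete)` complete frames are required;
  otherwise an `insufficient_support` condition is signalled. A training
  matrix with all rows identical signals `degenerate_basis`.
* Gaps are whole-marker events: a frame where only one or two of a
  marker's coordinates are missing is demoted to a full marker gap with
  a warning.
* A marker that shares no frames with any target cannot be assigned a
  distance weight; it receives 1e-6 — effectively excluded, but kept
  strictly positive so the weighted matrix stays well formed.
* In-memory missing values are `NA` in all three coordinates; zeros in
  input files are data, not gaps, except C3D invalid-point flags
  (negative residuals or all-zero points).

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run the three presets at full
length (4300/600/400 frames) with 50-replicate protocols for the method
comparison and 6–8 replicates per preset for the `w_mm` sensitivity
direction; exact-recovery checks use rank-3/4 noiseless trials of
150–500 frames. These sizes keep a complete run in the low minutes on a
single CPU while leaving the medians stable to well within the asserted
orderings.

## Known limitations

* Reconstruction quality degrades when the gap spans a movement regime
  absent from the complete frames (e.g. a running-only gap trained on
  walking frames) — inherent to a correlation-based method.
* No musculoskeletal constraints: reconstructed trajectories can
  violate segment lengths, and results should be inspected before
  downstream modelling.
* The C3D reader covers little-endian files with 3D point data only
  (no analog import); the `.mat` study-container reader handles
  uncompressed MAT v5 numeric arrays.
* Very small `sigma` combined with sparse marker sets can leave all
  neighbour weights near the exclusion floor; the reconstruction then
  rests on numerically tiny columns and becomes noisy.
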