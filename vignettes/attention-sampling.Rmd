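---
title: "Attention-guided patch sampling for whole-slide images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided patch sampling for whole-slide images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsisampler)
```

## The problem

A whole-slide image (WSI) of an H&E-stained colorectal resection is a
gigapixel object, but the quantities pathology cares about here — the
tumour region of interest (ROI) and the tumour–stroma ratio (TSR, a
prognostic marker) — are governed by a small part of it. Dense
tile-by-tile classification of every 224 px patch is the obvious
baseline and is expensive; this package implements an adaptive
alternative that spends classification effort where tumour has been
seen, plus everything needed to evaluate it without real slides.

The pipeline, in order:

1. **Sparse initial sampling.** The slide is covered by a coarse square
   grid (640, 768 or 1024 px boxes; 313, 376 or 502 μm at 0.49 μm/px).
   One 224 px patch is placed uniformly at random in each box; patches
   whose centre falls on background are dropped. Each patch is
   classified into one of nine tissue classes.
2. **False-positive correction.** Patches predicted *tumour* pass
   through a second, binary stage that separates tumour epithelium
   from normal epithelium — the documented failure mode of patch
   classifiers on tissue outside the tumour, where glandular normal
   epithelium mimics tumour.
3. **Densification.** Every grid box holding a tumour-classified patch
   receives four further patches per tumour patch, capped at five
   patches per box, each placed by re-drawing uniform positions until
   it overlaps no patch of the same box. One or two densification
   rounds are run.
4. **ROI prediction.** DBSCAN clusters the FP-corrected tumour patch
   centres (radius 2000 px, core threshold 3, i.e. a point plus at
   least two neighbours), rejecting sporadic isolated points as noise.
   Each cluster is outlined by a convex hull.
5. **Uniform ROI fill.** Boxes whose centre lies inside a hull are
   topped up to five patches, giving uniform higher density across the
   predicted ROI; boxes outside keep their sparse density. The new
   patches are classified, and the final ROI is re-estimated from all
   accumulated tumour points.
6. **TSR estimation.** TSR = T / (T + S) from the counts of patches
   classified tumour (T) and stroma/fibrosis (S), under four sampling
   strategies (below).

A tile-by-tile reference pipeline covers the slide with contiguous
224 px tiles in a single pass and shares every downstream stage, so
the comparison isolates the sampling strategy. Efficiency is compared
by patch counts, not wall-clock, to stay hardware-independent.

## The virtual-slide model

Real WSIs and trained CNNs are deliberately outside this package's
scope; both are replaced by contracts with simulated implementations.

A `virtual_slide` stores a label raster — one tissue class per
`raster_step` × `raster_step` block of level-0 pixels (default 32) —
instead of pixels. A patch's ground-truth class is the raster label
under its centre pixel, mirroring the convention by which pathologist
point annotations become patch labels. Patch content is never
rendered: every test exercises the sampling, clustering and estimation
machinery, not image analysis.

`generate_slide()` emulates one slide with known ground truth:

* an elliptical tissue section inside a background margin;
* a star-convex tumour ROI (a radial-harmonic-perturbed ellipse, 8–16
  harmonics with bounded total amplitude, so the region is connected
  and mostly convex — the single-ROI regime) whose polygon area is
  solved to hit the requested fraction of tissue area;
* known class composition inside the ROI, realized by quantile-slicing
  a smooth random field, so realized fractions match the request to
  within one raster cell while staying spatially clumped;
* normal tissue outside the ROI (stroma, muscle, inflammation, lumen),
  plus a contiguous band of **normal epithelium** at the tissue rim —
  the false-positive source;
* full determinism: the same parameters and seed are bit-identical.

Default parameters, chosen once as a plausible desk-scale stand-in for
a scanned resection: 20000 × 20000 px at 0.49 μm/px (a ~1 cm tissue
extent; real slides are larger, which only makes the boundary effects
discussed below milder), ROI fraction 0.15 of tissue area, inside-ROI
composition tumour 0.45 / stroma 0.35 / necrosis, lumen, inflammation,
mucin 0.05 each (area TSR 0.5625), normal-epithelium band 768 px. Two
different noise wavelength bands are used: 400–1600 px (0.2–0.8 mm)
inside the ROI, reflecting sub-millimetre intra-tumoral gland/stroma
intermixing, and 1500–6000 px outside, where tissue compartments are
coarser. With a single coarse band the synthetic "tumour" degenerates
into one lobe on one side of the ROI, which is not how colorectal
tumour texture is organised and starves half the ROI of detectable
tumour.

What the generator does **not** emulate: stain and texture appearance
(and therefore any real classifier's error structure), multi-focal
tumours, holes in the ROI, tissue folds and artefacts, and
tissue-versus-background detection on real scanners (for synthetic
slides background is known exactly). Passing tests therefore validate
the pipeline logic under a known error model, not end-to-end
performance on real slides.

## The simulated classifier

`make_confusion()` builds a row-stochastic confusion matrix: each of
the nine true classes has `overall_accuracy` (default 0.79, a typical
patch-classifier operating point) on the diagonal, with the remaining
mass spread over the other classes and extra weight on the
tumour/stroma pair, the dominant confusion in this domain. Two
ground-truth-only rows complete the model: background maps to
non-informative with certainty, and normal epithelium is called
tumour with probability `normal_epi_to_tumour_rate` (default 0.3).
The FP-correction stage is simulated from ground truth with
sensitivity and specificity defaulting to 0.927, the single accuracy
figure such binary correctors typically report; the two are exposed
separately because a real corrector's operating point need not be
symmetric.

One consequence worth stating plainly: this synthetic confusion
spreads part of its error as stroma→tumour calls scattered across the
whole section, which the FP stage (by design) does not touch. Real
CNN confusions concentrate errors inside the tumour region more than
this null model does, so the realistic-accuracy ROI Dice produced
here is pessimistic relative to published pipelines; the
perfect-classifier configuration isolates the sampling geometry.

## ROI estimation choices

* **DBSCAN** is implemented directly (grid-binned neighbour search plus
  breadth-first expansion over core points) with deterministic
  tie-breaking: clusters are connected components of core points
  numbered by smallest point index, and a border point joins the
  lowest-numbered cluster among its core neighbours. This makes the
  labelling order-independent and exactly checkable against a
  brute-force neighbour-counting oracle, which the test suite does on
  hundreds of random instances.
* **min_samples = 3** operationalizes "a point with multiple
  neighbours" as core: itself plus at least two others within 2000 px.
  It is a configuration parameter; results are somewhat sensitive to
  it at very sparse sampling.
* **Footprint hulls.** Each tumour point is the centre of a 224 px
  patch, so the pipeline outlines clusters with the convex hull of the
  patch footprint corners (centre ± 112 px) rather than of the bare
  centres. The hull of interior sample centres is a negatively biased
  estimator of region support — it under-covers by half a patch plus
  part of the sampling spacing — and the footprint hull corrects the
  patch-extent half of that bias with no free parameter.
  `build_hulls()` defaults to the plain point hull; the pipeline
  passes `expand_px = patch_px / 2`.
* **Final re-estimate.** The ROI fill uses the hulls from the pre-fill
  clustering, then the reported ROI is re-clustered from all
  accumulated FP-corrected tumour points, so the final estimate uses
  all available evidence (the tile-mode ROI is estimated the same
  way, keeping the two modes comparable).
* **Dice** is computed on areas, by rasterizing predicted and
  ground-truth polygons on the raster-cell lattice; both-empty is
  defined as perfect agreement (1), exactly one empty as 0. Raster
  convergence (step 16 vs 32) is tested to be < 0.02.

## TSR estimation

Four strategies, all using the two-stage classifier and
`TSR = T / (T + S)`:

* `uniform_roi` — 100 fresh patches by rejection sampling uniformly
  over the predicted hull union (centres ≥ 112 px from slide edges);
* `box_max_density` — 120 patches on a RandomSpot-style triangular
  lattice inside the 3 mm (6122 px) window of maximum tumour-point
  density, emulating the pathologist protocol. The lattice pitch is
  derived, not hard-coded: the largest integer pitch guaranteeing the
  requested point count for every random offset, floored at 224 px so
  adjacent spots cannot be near-duplicate patches. The density window
  is an axis-aligned square evaluated on a candidate lattice with
  stride window/4, ties broken to smallest (y, x);
* `sliding_mean` — the unweighted mean of per-window TSRs of the
  already-sampled patches over 3 mm windows (stride window/2, a
  window participates when its centre is in the hull union and it
  holds ≥ 10 tumour+stroma patches; both knobs are exposed because no
  canonical values exist);
* `gt_locations` — classification at the ground-truth annotation
  points, the ceiling any location-prediction scheme could reach.
  `uniform_roi` draws fresh patches rather than re-using pipeline
  patches, so its sample size is ~100 regardless of pipeline density
  — an interpretation, recorded here.

Each synthetic slide carries a designated ground-truth point layout
(`gt_sample_points()`): 50 RandomSpot-style points in the 3 mm window
of maximum ground-truth tumour density, emulating the pathologist
workflow. The point-sampled ground-truth TSR — the totals of tumour
and stroma labels at those points — is the reference for RMSE and
signed mean error (ground truth minus estimate), matching how such
ground truth is produced in practice; the exhaustive-count area TSR is
reported alongside.

## Numerical and degenerate-input choices

* Coordinates are 0-based level-0 pixels, x rightward, y downward,
  half-open intervals everywhere; two patches overlap iff their
  half-open squares intersect with positive area, so edge-touching
  patches do not overlap.
* Patch top-left corners are drawn uniformly over the grid box and may
  extend past the box's right/bottom edge (but never the slide edge);
  confining whole patches to a 640 px box would make five
  non-overlapping patches impossible, contradicting the per-box cap.
* Overlap is checked only against patches of the same box; cross-box
  checks would make the cap unreachable near dense borders.
* Placement re-draws a slot up to `max_retries` (100) times, then
  falls back to exact uniform sampling over the enumerated admissible
  positions; a slot is skipped, with a logged warning, only when no
  admissible position exists. Such genuine deadlocks are real —
  four patches can block every position for a fifth (measured at
  roughly 1–2% of forced top-up-to-five scenarios) — and rim boxes
  holding only a sliver of tissue can admit fewer than five patches.
* The FP stage leaves tumour-predicted patches untouched when their
  ground truth is neither tumour nor normal epithelium, and relabels
  removed false positives as normal epithelium rather than discarding
  them, so the correction is auditable downstream.
* Degenerate inputs raise classed conditions (`wsis_parameter_error`,
  `wsis_bounds_error`, `wsis_format_error`, `wsis_degenerate_error`,
  `wsis_undefined_metric_error`, `wsis_input_error`): TSR with
  T + S = 0 and metrics over empty sets are undefined-metric errors, a
  slide with no tumour completes with an empty ROI and Dice 0, and
  clusters with fewer than three non-collinear points are dropped from
  hull construction with a log message.

## Problem sizes used in the tests

The shipped test-and-acceptance configuration uses 20 synthetic slides
at the default 20000 px size, the 640 px grid, and both one and two
densification rounds; DBSCAN is cross-checked against its brute-force
oracle on 200 random instances of up to 200 points, and the sampling
invariants are scanned over 1000 seeded runs. These sizes were chosen
to give stable means (binomial and seed-to-seed noise well below the
effects being asserted) while staying comfortable on a single CPU.

## Known limitations

* The convex hull cannot represent concave ROIs or holes; concavities
  of the star-convex ground truth are bridged, which the Dice score
  penalizes honestly.
* A 9-class confusion matrix with a single global accuracy is a crude
  null model of a real classifier (no spatial correlation of errors,
  no class-specific accuracies beyond the tumour/stroma pair).
* Densification is capped at five patches per box at every stage, so
  a second round adds little once boxes are saturated; the cap keeps
  patch budgets predictable and is asserted as an invariant.
* TSR windows are axis-aligned squares; the 3 mm window of a glass
  protocol is orientation-free.
* Real-slide use requires a region reader and classifier behind the
  declared contracts; neither ships here.
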