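# wsisampler

Attention-guided patch sampling and tumour–stroma-ratio estimation for
whole-slide images (WSIs), with a fully synthetic test bed.

## What this is for

Gigapixel H&E slides are usually analysed by classifying every 224 px
tile — tens of thousands of classifier calls per slide, most of them
spent on tissue that carries no tumour. `wsisampler` implements an
adaptive alternative for pathology image-analysis developers: sample
sparsely on a coarse grid, densify wherever a patch classifier reports
*tumour*, correct the classifier's documented false positives (normal
epithelium outside the tumour mimicking tumour), outline the tumour
region of interest (ROI) by clustering the corrected tumour points,
then sample the predicted ROI uniformly. The end products per slide
are a predicted ROI polygon and tumour–stroma-ratio (TSR) estimates,
at a fraction of the tile-by-tile patch budget.

Real slides and trained CNNs are deliberately behind contracts: a
synthetic virtual-slide generator (label raster + known ground-truth
ROI and composition) and a confusion-matrix-simulated 9-class
classifier make the entire pipeline testable end to end on a laptop.

## The core quantities

* Patch classification: 9 tissue classes; a patch's ground truth is
  the class under its centre pixel.
* False-positive correction: a binary stage on tumour-predicted
  patches with sensitivity/specificity (default 0.927 each).
* ROI: DBSCAN over FP-corrected tumour points (eps = 2000 px,
  min_samples = 3) → convex hull per cluster (over patch footprints);
  agreement with ground truth scored by Dice/F1,
  2|P∩G| / (|P| + |G|), on rasterized areas.
* TSR: `TSR = T / (T + S)` from tumour (T) and stroma/fibrosis (S)
  patch counts, by four sampling strategies: 100 uniform patches in
  the predicted ROI; 120 patches on a RandomSpot-style hexagonal
  lattice in the 3 mm (6122 px) window of maximum tumour density; the
  mean over sliding 3 mm windows; and the ground-truth annotation
  locations (the theoretical ceiling).
* Errors across a slide set: `RMSE = sqrt(mean((TSR_GT - TSR_est)^2))`
  and signed mean error `ME = mean(TSR_GT - TSR_est)`.

## Worked example

```r
library(wsisampler)

s <- generate_slide(seed = 7)     # 20000 x 20000 px virtual slide
s
#> <virtual_slide> 20000 x 20000 px @ 0.49 um/px (raster step 32)
#>   ground-truth ROI: 256-vertex polygon, 15.0% of tissue area
#>   inside-ROI composition: tumour=0.45, stroma_fibrosis=0.35, necrosis=0.05,
#>     lumen=0.05, inflammation=0.05, mucin=0.05
gt_area_tsr(s)
#> [1] 0.5625

r <- run_attention_pipeline(s, pipeline_config(seed = 11,
                                               resample_iterations = 2))
r
#> <wsi_run> attention mode, 1332 patches (initial=539, resample_1=259,
#>                                         resample_2=0, roi_fill=534)
#>   predicted ROI: 3 hull(s); Dice vs ground truth: 0.600
#>   tumour inside ROI: 64.1% pre-FPC, 71.2% post-FPC
#>   TSR [uniform_roi]: 0.373 (T=25, S=42)
#>   TSR [box_max_density]: 0.500 (T=33, S=33)
#>   TSR [sliding_mean]: 0.351 (T=616, S=1073)
#>   TSR [gt_locations]: 0.594 (T=19, S=13)
#>   ground truth: point TSR 0.649, area TSR 0.563
```

Reading the output: the slide was generated with a tumour ROI covering
15% of the tissue and an exhaustive-count (area) TSR of 0.5625. With
the default simulated classifier (79% accuracy, 30% normal-epithelium
to tumour confusion, 92.7% FP corrector) the attention pipeline spent
1332 patches — the initial sparse pass (539), densification around
detected tumour (259; the second round adds nothing once boxes hit the
5-patch cap), and the uniform ROI fill (534). FP correction raised the
fraction of tumour predictions lying inside the true ROI from 64.1% to
71.2%. The TSR at the pathologist-style 3 mm max-density window
(`box_max_density`, 0.500) and at the ground-truth points
(`gt_locations`, 0.594) bracket the point-sampled ground truth
(0.649); the ROI-wide methods read lower because the predicted hull
also covers stroma-rich margins. A perfect-classifier configuration
(`accuracy = 1, normal_epi_to_tumour_rate = 0, fp_* = 1`) isolates the
sampling geometry and reaches Dice ≈ 0.94 on the same slides.

The tile-by-tile reference on the same slide costs ~4700 patches —
about 3.5× the attention budget:

```r
t <- run_tiled_reference(s, pipeline_config(box_px = 224, seed = 11))
compare_runs(r, t)$patch_count_ratio
```

A thin CLI wraps the same functions
(`generate` / `run` / `tiles` / `evaluate` / `compare`); after
installation see `system.file("exec", "wsisampler", package = "wsisampler")`.

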