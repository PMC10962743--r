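# weakbox3d

Weak 3D box labels and lesion-level detection evaluation for CT volumes.

## The problem

Rare tumors such as pheochromocytomas and paragangliomas (PPGLs) are found
throughout the trunk, vary from about 1 to 15 cm in diameter, and are
routinely marked by radiologists with a single RECIST-style measurement: a
2D bounding box on the one axial slice showing the lesion's maximum
diameter. Voxel-wise 3D contours — what a segmentation network would like to
train on — are rarely available. `weakbox3d` supports the workflow that
bridges this gap:

1. **Weak label construction.** Each single-slice 2D box is extended to the
   three adjacent slices above and below (a 7-slice 3D box, clipped at the
   volume ends), rasterized, and merged with a body-region mask into a
   3-class training label map (0 = background, 1 = body, 2 = lesion). The
   body class counters the extreme foreground/background imbalance that a
   lesion-only mask would create.
2. **Lesion-level detection evaluation.** Hard prediction masks are broken
   into 3D connected components (26-connectivity by default). A ground-truth
   lesion counts as a **true positive** if it shares at least one voxel with
   any predicted component; a predicted component that overlaps no
   ground-truth lesion is a **false positive**; a missed ground-truth lesion
   is a **false negative**. Detection metrics are

       precision = TP / (TP + FP),    recall = TP / (TP + FN),

   reported pooled over the dataset and as per-patient distributions (mean,
   population SD, median, 25th–75th percentile IQR). Small predicted
   components can be excluded by a voxel-count size threshold (applied to
   predictions only, never to ground truth), and
   `percentile_size_threshold()` implements the selection rule that picks
   the threshold as a percentile (e.g. the 15th) of predicted lesion sizes.
3. **Synthetic phantoms.** A seeded generator produces CT-like volumes
   (ellipsoidal soft-tissue body in air, ellipsoidal lesions spanning tens to
   thousands of voxels, Gaussian HU noise), auto-derives the per-lesion 2D
   maximum-area boxes, and degrades ground truth into "predictions" with an
   exactly known number of dropped lesions and injected spurious blobs — so
   every stage of the pipeline is testable without patient data.

The intended users are researchers evaluating lesion-detection models (or
building weak labels for them) who need the bookkeeping — component
extraction, overlap matching, thresholding, per-patient aggregation — to be
exactly reproducible.

## Worked example

```r
library(weakbox3d)

# a phantom with 4 lesions, and a degraded "prediction" that drops one
# lesion and injects two small spurious blobs
ph   <- generate_phantom(phantom_spec(n_lesions = 4, seed = 42))
pred <- degrade_prediction(ph$gt,
          degradation_spec(n_drop = 1, n_inject = 2, seed = 42))

extract_components(ph$gt)$voxels
#> [1] 667 273 451 510                  # true lesion sizes in voxels
attr(pred, "injected")$voxels
#> [1] 126  82                          # both spurious blobs are small

evaluate(ph$gt, pred, size_threshold = 0, scan_id = "phantom42")$metrics
#>     scan_id n_gt tp fp fn precision recall
#> 1 phantom42    4  3  2  1       0.6   0.75

evaluate(ph$gt, pred, size_threshold = 250, scan_id = "phantom42")$metrics
#>     scan_id n_gt tp fp fn precision recall
#> 1 phantom42    4  3  0  1         1   0.75
```

The 250-voxel size threshold removes exactly the two sub-250-voxel spurious
blobs: precision rises from 0.60 to 1.00 while recall is unchanged at 0.75 —
the dropped lesion stays a false negative because ground truth is never
filtered. Weak labels come from the same phantom:

```r
boxes <- derive_2d_boxes(ph$gt, scan_id = "phantom42")
boxes[[1]]
#> <box2d> scan phantom42, slice z=35, rows [31,40), cols [35,46)
lm <- make_weak_labels(boxes, ph$body, scan_id = "phantom42")
table(lm)
#>      0      1      2
#> 420400 166643   2781                 # air / body / weak lesion boxes
```

A command-line interface wrapping these functions ships in
`inst/cli/weakbox3d` with verbs `phantom`, `make-labels`, `body`, `segment`,
`eval` and `run`; `run` executes the whole pipeline (body mask → weak labels
→ baseline or external predictions → evaluation) from a YAML config and
writes a self-describing run directory with per-scan and summary CSV
reports.

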