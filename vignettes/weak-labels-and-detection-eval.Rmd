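---
title: "Weak 3D box labels and lesion-level detection evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak 3D box labels and lesion-level detection evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weakbox3d)
```

## Overview

`weakbox3d` implements two halves of a weakly supervised lesion-detection
workflow for CT: construction of weak 3D training labels from single-slice
2D box annotations, and a lesion-level (component-level, not voxel-level)
detection evaluation protocol for hard prediction masks. This vignette
documents the underlying procedures, their assumptions, the tunable
parameters and the numerical choices, so that every number the package
produces can be traced to a stated rule.

## Coordinate conventions

Volumes are plain R arrays with `dim = c(rows, cols, slices)`; the third
margin is the axial (z) axis. Everything user-facing in R is 1-based and
inclusive, as R users expect. The annotation interchange format — the CSV
with header `scan_id,z,row_min,col_min,row_max,col_max` and the `box2d`
fields — instead uses 0-based indices and half-open intervals, which is the
convention annotation tooling typically exports and is unambiguous about box
widths (`row_max - row_min` is the extent in voxels). The conversion happens
exactly once, at rasterization. Annotators counting 1-based must subtract
one when exporting; this is stated in the `box2d()` documentation because it
is the single most likely off-by-one in practice.

## Weak label construction

A radiologist-style annotation is one rectangle on the axial slice where the
lesion shows its maximum diameter. `extend_box_to_3d()` copies that
rectangle onto the `radius = 3` adjacent slices above and below, giving a
7-slice 3D box:

* `z_min = max(0, z - radius)`, `z_max = min(n_slices, z + radius + 1)`
  (half-open). Clipping at the volume ends, rather than rejecting edge
  annotations, is a deliberate choice: scans are routinely cropped and an
  annotation near the first or last slice must remain usable. The spanned
  slice count is therefore `min(7, ...)`, and always contains the annotated
  slice.
* The in-plane extent is never altered.

`rasterize_weak_boxes()` marks a voxel foreground iff it lies in at least
one box; overlapping boxes from distinct lesions merge in the raster
(lesion identity is deliberately not preserved at voxel level, because the
evaluation downstream is component-based). `merge_with_body()` then produces
the 3-class label map with the fixed encoding 0 = background, 1 = body,
2 = lesion, and the lesion class wins every conflict: a box spilling past
the body surface into air keeps code 2 there. We considered clipping weak
boxes to the body mask and decided against it — the box is the annotated
evidence, the body mask is an automatically produced auxiliary, and letting
the auxiliary erode the annotation would silently shrink training labels.
No clipping option is exposed by default. We also assume one box per lesion
per annotated slice; multiple boxes simply rasterize as a union.

The body class exists to fight class imbalance when these maps are used to
train a segmentation model: with lesions alone, foreground would be a
vanishing fraction of a chest–abdomen–pelvis volume.

## Body-region mask

`load_body_mask()` accepts any external segmentation (every nonzero label
becomes body), so multi-organ outputs of whole-body segmentation tools work
unchanged; we collapse them to a binary body-vs-air mask since that is the
only distinction the label map uses. `segment_body_fallback()` is this
package's own built-in alternative so the pipeline has no hard external
dependency: threshold at −500 HU (comfortably between air at about −1000 HU
and fat/soft tissue at −100 HU and above), keep the largest 26-connected
component (removes the scanner table and cables), and fill internal holes
slice-wise (keeps lungs and bowel gas inside the body). The result carries a
`provenance` attribute (`external-file` or `fallback`) so a run directory
records which source produced it.

## Detection evaluation protocol

**Components.** `extract_components()` labels 3D connected components;
connectivity defaults to 26 (the full 3×3×3 neighborhood), the most
permissive choice, which avoids splitting blocky or box-like predictions
into accidental fragments. 6 and 18 are available.

**Matching.** A ground-truth lesion is a true positive iff it shares at
least one voxel with any predicted component; a predicted component is a
false positive iff it overlaps no ground-truth lesion. TP and FN are counted
over ground-truth lesions, FP over predictions, independently — so matching
is one-to-many in both directions: one large prediction covering two lesions
yields two TPs and no FP; two predictions on one lesion yield one TP and no
FP. This convention keeps `TP + FN = number of GT lesions` as an exact
invariant at every threshold and is the only reading consistent with
published detection tables in which TP and FN are constant across prediction
filters while FP varies. The one-voxel criterion is deliberately permissive;
an optional `min_overlap_frac` knob (fraction of the ground-truth component
volume) tightens it but defaults off.

**Size threshold.** `filter_by_size()` retains predicted components with
voxel count strictly greater than the threshold. The boundary had to be
chosen (either convention excludes "small" lesions); strict-greater is
documented and configurable by passing `threshold - 1` if inclusive behavior
is wanted. The filter applies to predictions only — ground truth is never
filtered, so raising the threshold can only convert TPs into FNs by removing
the matching prediction, never delete a ground-truth lesion.
`percentile_size_threshold()` implements the percentile selection rule with
linear interpolation between order statistics (`stats::quantile` type 7),
making the rule deterministic: for sizes 10, 20, …, 100 the 15th percentile
is 23.5.

**Per-scan metrics.** precision = TP/(TP+FP), recall = TP/(TP+FN). An
undefined ratio (no predictions, or no ground-truth lesions) is `NA`, never
a silent 0/0. The one convention on top: a scan with no lesions *and* no
predictions scores precision = recall = 1, since the empty answer is
correct. This matters only for synthetic edge cases — any real test cohort
has lesions in every scan.

**Cohort aggregation.** `cohort_summary()` reports (a) pooled metrics
recomputed from summed TP/FP/FN — the dataset-level view — and (b) the
per-scan distribution: mean, standard deviation with population denominator
n (the cohort is the whole population of interest, not a sample to
extrapolate from), median, and the 25th–75th percentile IQR, all with
quantile type 7. Scans with an undefined metric are excluded from the
distribution statistics and counted in `n_excluded`; if every scan is
undefined the statistic itself is `NA`. `summary_delta()` differences two
summaries statistic-by-statistic (percentage-point differences when the
inputs are percentages).

## Synthetic phantom generator

`phantom_spec()` defaults describe the test conditions used throughout the
package's own tests:

| parameter | default | rationale |
|---|---|---|
| `shape` | 96×96×64 voxels | desk-scale stand-in for a trunk CT grid |
| `background_hu` | −1000 HU | air |
| `body_hu` | 40 HU | soft tissue |
| `lesion_hu` | 60–90 HU | enhancing soft-tissue mass, above body tissue |
| `lesion_semiaxes` | 2–8 voxels | component volumes from ≈30 to ≈2100 voxels, spanning well below and above a 250-voxel size threshold, emulating the 1–15 cm spread of real lesions at coarse spacing |
| `noise_sigma` | 5 HU | realistic quantum-noise magnitude; enough to create spurious threshold crossings |

Lesions are placed by rejection sampling (capped at `max_attempts = 1000`;
failure is an error, never a silent undercount) fully inside the body with a
two-voxel margin from its surface and at least a one-voxel gap between
lesions, so the ground truth has exactly `n_lesions` 26-connected
components. All outputs are pure functions of (spec, seed), and generation
saves and restores the caller's RNG state.

`derive_2d_boxes()` operationalizes "the slice showing the maximum
diameter" as the slice of maximum in-plane component area, with ties broken
toward the smallest slice index. For the convex (ellipsoidal) lesions the
generator produces, the maximum-area slice and the maximum-diameter slice
coincide; the tie-break makes the choice deterministic.

`degrade_prediction()` turns ground truth into a synthetic prediction with
*exactly known* error counts: `n_drop` lesions removed, `n_inject` spurious
ellipsoidal blobs added, and each surviving lesion dilated or eroded by a
random radius up to `jitter`. Three geometric guarantees make the recovery
exact: jittered growth never enters another ground-truth lesion (it would
otherwise match it), injected blobs keep a one-voxel gap from everything
(they would otherwise merge with a real component and stop being a separate
false positive), and a component annihilated by erosion is replaced by its
most interior voxel (it must keep overlapping its source). Consequently
evaluation reports FP = `n_inject` and FN = `n_drop` identically, which is
the property the acceptance checks exercise over 50 seeded pairs.

**What the phantoms do not emulate.** No organs, no necrotic lesion cores,
no macroscopic fat/hemorrhage/calcification, no scanner artifacts, no
anisotropic voxel spacing. Passing tests on phantoms therefore validate the
*bookkeeping* — label geometry, component analysis, matching, thresholding,
aggregation — not the clinical difficulty of detecting real lesions, and say
nothing about how a trained model generalizes.

## The baseline segmenter and external adapters

`baseline_segment()` is a transparent HU-window rule (default window 55–90
HU, bracketing the phantom lesion intensities): lesion = in-window voxels
inside the body, minus candidate components touching the body surface (a
pure threshold otherwise picks up the bright partial-volume rim). It exists
so `run_pipeline()` is executable end to end on a workstation; it is a
baseline, not a model. Trained segmenters enter through the
external-prediction seam: `segmenter = <directory>` consumes one NIfTI mask
per scan, and `adapter_metadata()` records — as provenance only, nothing is
executed — the training recipe associated with externally produced nnU-Net
predictions (3D full-resolution, 5 folds, 1000 epochs, equally weighted
binary cross-entropy + soft Dice, SGD at initial learning rate 10⁻³, batch
size 1, fold-ensembled inference) and a command template for producing a
body mask with TotalSegmentator. The fold-ensembling rule for hard masks is
not part of the recorded metadata's semantics here, since inference happens
outside the package. The display window (center 50, width 450 HU) sometimes
used when annotating is likewise recorded in run configs for provenance; no
computation depends on it.

## Known limitations

* Weak 7-slice boxes over-estimate small lesions (the box corners are not
  lesion) and under-estimate lesions thicker than 7 slices; a model trained
  on them inherits both biases. The package quantifies the second effect:
  for phantom lesions at most 7 slices thick, weak labels overlap every
  lesion, while a thicker lesion's weak box provably covers only part of it
  (this shortfall is asserted in the test suite rather than hidden).
* Only detection metrics are provided. With box ground truth, voxel-level
  Dice or boundary metrics would measure agreement with boxes, not with
  tumors, so they are deliberately out of scope, as are FROC curves
  (predictions are hard masks without confidence scores).
* Evaluation is in voxels, not mm³; with anisotropic or varying voxel
  spacing a fixed voxel-count threshold corresponds to different physical
  volumes on different scans.

## Problem sizes and runtime choices

The test suite and the acceptance script run at sizes chosen to make the
full loop fast on a single core: phantoms of 96×96×64 (the generator
default) or 48×48×40 voxels, cohorts of 3–20 scans, 50 degradation-recovery
pairs, and 100 randomized oracle comparisons on grids up to 20³ (where the
exhaustive pairwise-overlap oracle and the BFS flood-fill oracle are
affordable). Connected-component labeling, slice-wise hole filling and
Chebyshev morphology are implemented in C++ (Rcpp) since no suitable 3D
implementation with selectable 6/18/26 connectivity was available among the
package's dependencies; everything else is plain R on top of `RNifti` I/O
and `stats` primitives.
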