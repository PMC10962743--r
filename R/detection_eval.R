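#' Extract 3D connected components from a binary lesion mask
#'
#' Realizes "lesions" as discrete objects: maximal sets of foreground voxels
#' mutually reachable under the chosen 3D neighborhood (6 = faces, 18 = faces
#' + edges, 26 = full cube). The default 26 is the most permissive and avoids
#' splitting box-like predictions.
#'
#' @param mask binary 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param source optional tag, `"gt"` or `"pred"`, carried in the result.
#' @return A data.frame of class `lesion_components` with one row per
#'   component: `id`, `voxels`, tight bounding box (`row_min`..`z_max`,
#'   1-based inclusive) and centroid (`centroid_row`, `centroid_col`,
#'   `centroid_z`). The integer label array is attached as attribute
#'   `"labels"`.
#' @export
extract_components <- function(mask, connectivity = 26L, source = NULL) {
  mask <- as_mask(mask)
  dims <- check_dims3(mask)
  labels <- .label_components_cpp(mask, dims, as.integer(connectivity))
  n <- attr(labels, "n_components")
  if (n == 0L) {
    df <- data.frame(id = integer(), voxels = integer(),
                     row_min = integer(), row_max = integer(),
                     col_min = integer(), col_max = integer(),
                     z_min = integer(), z_max = integer(),
                     centroid_row = numeric(), centroid_col = numeric(),
                     centroid_z = numeric())
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    coord <- arrayInd(idx, dims)
    df <- data.frame(
      id = seq_len(n),
      voxels = tabulate(lab, nbins = n),
      row_min = as.integer(tapply(coord[, 1], lab, min)),
      row_max = as.integer(tapply(coord[, 1], lab, max)),
      col_min = as.integer(tapply(coord[, 2], lab, min)),
      col_max = as.integer(tapply(coord[, 2], lab, max)),
      z_min = as.integer(tapply(coord[, 3], lab, min)),
      z_max = as.integer(tapply(coord[, 3], lab, max)),
      centroid_row = as.numeric(tapply(coord[, 1], lab, mean)),
      centroid_col = as.numeric(tapply(coord[, 2], lab, mean)),
      centroid_z = as.numeric(tapply(coord[, 3], lab, mean)))
  }
  rownames(df) <- NULL
  structure(df, class = c("lesion_components", "data.frame"),
            labels = labels, connectivity = as.integer(connectivity),
            source = source)
}

#' Filter predicted components by voxel size
#'
#' Keeps components whose voxel count is strictly greater than `threshold`
#' (so `threshold = 0` keeps everything); order is preserved. In the
#' evaluation protocol this filter is applied to predictions only, never to
#' ground truth.
#'
#' @param components a `lesion_components` data.frame (or any data.frame with
#'   a `voxels` column).
#' @param threshold minimum voxel count, exclusive.
#' @return The retained rows, attributes preserved.
#' @export
filter_by_size <- function(components, threshold) {
  stopifnot(threshold >= 0)
  keep <- components$voxels > threshold
  out <- components[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("labels", "connectivity", "source"))
    attr(out, a) <- attr(components, a)
  class(out) <- class(components)
  out
}

#' Percentile of the predicted lesion-size distribution
#'
#' Threshold-selection rule: returns the linear-interpolation percentile
#' (order statistics interpolated, `stats::quantile` type 7) of the component
#' voxel counts, e.g. the 15th percentile of predicted lesion sizes as a
#' candidate size threshold.
#'
#' @param pred_components a `lesion_components` data.frame or a numeric
#'   vector of voxel counts.
#' @param percentile percentile in \[0, 100\] (default 15).
#' @return Voxel-count threshold (numeric scalar).
#' @export
percentile_size_threshold <- function(pred_components, percentile = 15) {
  sizes <- if (is.data.frame(pred_components)) pred_components$voxels
           else as.numeric(pred_components)
  if (length(sizes) == 0L)
    stop_weakbox("no predicted components: cannot compute a size percentile",
                 class = "weakbox3d_insufficient_data_error")
  stopifnot(percentile >= 0, percentile <= 100)
  unname(quantile(sizes, probs = percentile / 100, type = 7))
}

#' @noRd
lesion_mask_from <- function(x, lesion_code = CODE_LESION, arg = "mask") {
  if (is.logical(x)) return(x)
  vals <- unique(as.vector(x))
  m <- if (all(vals %in% c(0, 1))) x != 0 else x == lesion_code
  dim(m) <- dim(x)
  m
}

#' Match ground-truth and predicted lesions by voxel overlap
#'
#' The lesion-level matching rule: a ground-truth component is a true
#' positive iff it shares at least one voxel with any predicted component; a
#' predicted component is a false positive iff it overlaps no ground-truth
#' component. Matching is one-to-many in both directions: one large
#' prediction covering two GT lesions yields two TPs and no FP, and several
#' predictions on one GT lesion yield one TP and no FPs. An optional
#' minimum-overlap fraction (of the GT component volume) tightens the
#' criterion; it defaults off.
#'
#' @param gt ground-truth binary mask or `lesion_components` (with its label
#'   array attribute).
#' @param pred prediction binary mask or `lesion_components`.
#' @param connectivity component connectivity when masks are given.
#' @param min_overlap_frac minimum shared fraction of the GT component volume
#'   for a pair to count (default 0 = any shared voxel).
#' @return An object of class `match_table`: data.frames `gt` and `pred` with
#'   a `matched` flag, the `overlaps` pair table (`gt_id`, `pred_id`,
#'   `voxels`), and counts `tp`, `fp`, `fn`.
#' @export
match_lesions <- function(gt, pred, connectivity = 26L,
                          min_overlap_frac = 0) {
  gt_comp <- if (inherits(gt, "lesion_components")) gt
             else extract_components(gt, connectivity, source = "gt")
  pred_comp <- if (inherits(pred, "lesion_components")) pred
               else extract_components(pred, connectivity, source = "pred")
  gt_lab <- attr(gt_comp, "labels")
  pred_lab <- attr(pred_comp, "labels")
  if (!identical(dim(gt_lab), dim(pred_lab)))
    stop_weakbox("ground-truth shape (%s) does not match prediction shape (%s)",
                 paste(dim(gt_lab), collapse = "x"),
                 paste(dim(pred_lab), collapse = "x"),
                 class = "weakbox3d_structure_error")
  # Components may have been size-filtered: only retained ids participate.
  gt_keep <- gt_lab %in% gt_comp$id & gt_lab > 0L
  pred_keep <- pred_lab %in% pred_comp$id & pred_lab > 0L
  both <- which(gt_keep & pred_keep)
  if (length(both)) {
    pairs <- stats::aggregate(
      list(voxels = rep(1L, length(both))),
      by = list(gt_id = gt_lab[both], pred_id = pred_lab[both]), FUN = sum)
    if (min_overlap_frac > 0) {
      gt_size <- gt_comp$voxels[match(pairs$gt_id, gt_comp$id)]
      pairs <- pairs[pairs$voxels >= min_overlap_frac * gt_size, , drop = FALSE]
    }
  } else {
    pairs <- data.frame(gt_id = integer(), pred_id = integer(),
                        voxels = integer())
  }
  gt_df <- as.data.frame(gt_comp)
  pred_df <- as.data.frame(pred_comp)
  gt_df$matched <- gt_df$id %in% pairs$gt_id
  pred_df$matched <- pred_df$id %in% pairs$pred_id
  tp <- sum(gt_df$matched)
  structure(list(gt = gt_df, pred = pred_df,
                 overlaps = pairs[order(pairs$gt_id, pairs$pred_id), ,
                                  drop = FALSE],
                 tp = tp, fn = nrow(gt_df) - tp,
                 fp = sum(!pred_df$matched)),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat(sprintf("<match_table> %d GT, %d predicted components: TP=%d FP=%d FN=%d\n",
              nrow(x$gt), nrow(x$pred), x$tp, x$fp, x$fn))
  invisible(x)
}

#' Lesion-level precision and recall for one scan
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN), both as proportions
#' in \[0, 1\]. An undefined denominator yields `NA`, never a silent 0/0 —
#' except the fully empty scan (no GT lesions and no predictions), which
#' scores precision = recall = 1 by convention. Pass either a
#' [match_lesions()] result or explicit counts.
#'
#' @param x a `match_table`, or `NULL` when giving counts directly.
#' @param tp,fp,fn explicit counts (used when `x` is `NULL`).
#' @param scan_id optional scan identifier for the row.
#' @return One-row data.frame: `scan_id`, `n_gt`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
#' @examples
#' scan_metrics(tp = 98, fp = 59, fn = 55)  # precision 0.624, recall 0.641
scan_metrics <- function(x = NULL, tp = NULL, fp = NULL, fn = NULL,
                         scan_id = NA_character_) {
  if (!is.null(x)) {
    stopifnot(inherits(x, "match_table"))
    tp <- x$tp; fp <- x$fp; fn <- x$fn
  }
  stopifnot(!is.null(tp), !is.null(fp), !is.null(fn),
            tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) {
    precision <- 1; recall <- 1  # empty scan, empty prediction: perfect
  } else {
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  }
  data.frame(scan_id = scan_id, n_gt = tp + fn, tp = tp, fp = fp, fn = fn,
             precision = precision, recall = recall,
             stringsAsFactors = FALSE)
}

#' Aggregate per-scan detection metrics over a cohort
#'
#' Two complementary views, mirroring how detection studies report results:
#' pooled (dataset-level) precision/recall recomputed from the summed TP/FP/FN
#' counts, and per-scan (patient-level) distribution statistics — mean,
#' standard deviation (population denominator n), median and the 25th–75th
#' percentile IQR — over scans where the metric is defined. Scans with an
#' undefined value (e.g. no predictions at all) are excluded from the
#' distribution statistics and counted in `n_excluded`.
#'
#' @param per_scan data.frame of [scan_metrics()] rows (one per scan).
#' @return An object of class `cohort_summary`: `pooled` (one-row data.frame)
#'   and `stats` (one row per metric with mean/sd/median/q25/q75).
#' @export
cohort_summary <- function(per_scan) {
  stopifnot(is.data.frame(per_scan), nrow(per_scan) >= 1)
  pooled <- scan_metrics(tp = sum(per_scan$tp), fp = sum(per_scan$fp),
                         fn = sum(per_scan$fn), scan_id = "pooled")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  stat_row <- function(metric) {
    v <- per_scan[[metric]]
    def <- v[!is.na(v)]
    if (length(def) == 0L)
      return(data.frame(metric = metric, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                        n_defined = 0L, n_excluded = length(v)))
    q <- unname(quantile(def, c(0.25, 0.5, 0.75), type = 7))
    data.frame(metric = metric, mean = mean(def), sd = pop_sd(def),
               median = q[2], q25 = q[1], q75 = q[3],
               n_defined = length(def),
               n_excluded = length(v) - length(def))
  }
  structure(list(pooled = pooled,
                 stats = rbind(stat_row("precision"), stat_row("recall")),
                 n_scans = nrow(per_scan)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d scans; pooled TP=%d FP=%d FN=%d, precision %.1f%%, recall %.1f%%\n",
              x$n_scans, x$pooled$tp, x$pooled$fp, x$pooled$fn,
              100 * x$pooled$precision, 100 * x$pooled$recall))
  s <- x$stats
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s mean %.1f%%  sd %.1f%%  median %.1f%%  IQR %.1f%% - %.1f%%  (n=%d, excluded %d)\n",
                s$metric[i], 100 * s$mean[i], 100 * s$sd[i],
                100 * s$median[i], 100 * s$q25[i], 100 * s$q75[i],
                s$n_defined[i], s$n_excluded[i]))
  invisible(x)
}

#' Difference two cohort summaries (or summary statistics)
#'
#' Reports how much each summary statistic changed between two evaluation
#' settings (e.g. with and without a prediction-size threshold), as `after -
#' before`. For metrics expressed as percentages the result is in percentage
#' points: a median precision moving from 66.7 to 84.9 is an improvement of
#' 18.2 points.
#'
#' @param after,before two [cohort_summary()] objects, or two named numeric
#'   vectors of statistics on the same scale.
#' @return Same shape as the inputs, holding `after - before`.
#' @export
#' @examples
#' summary_delta(c(median_precision = 84.9), c(median_precision = 66.7))
summary_delta <- function(after, before) {
  if (is.numeric(after) && is.numeric(before)) {
    stopifnot(length(after) == length(before))
    return(after - before)
  }
  stopifnot(inherits(after, "cohort_summary"),
            inherits(before, "cohort_summary"))
  stat_cols <- c("mean", "sd", "median", "q25", "q75")
  stats <- after$stats
  stats[stat_cols] <- after$stats[stat_cols] - before$stats[stat_cols]
  stats$n_defined <- stats$n_excluded <- NULL
  pooled_cols <- c("tp", "fp", "fn", "precision", "recall")
  pooled <- after$pooled
  pooled[pooled_cols] <- after$pooled[pooled_cols] - before$pooled[pooled_cols]
  list(pooled = pooled, stats = stats)
}

#' Evaluate a prediction mask against ground truth for one scan
#'
#' The full per-scan protocol: take the lesion class out of a (possibly
#' multi-class) prediction, extract 3D components from prediction and ground
#' truth, drop predicted components at or below the size threshold (ground
#' truth is never filtered, so the filter can remove FPs but never create
#' FNs), match by voxel overlap, and compute precision/recall.
#'
#' @param gt_mask ground-truth lesion mask (binary, or a label map from which
#'   `lesion_code` is taken).
#' @param pred prediction: binary mask or integer label map.
#' @param size_threshold prediction voxel-count threshold, exclusive
#'   (default 0 = keep all).
#' @param lesion_code integer code of the lesion class in label maps
#'   (default 2).
#' @param connectivity component connectivity (default 26).
#' @param min_overlap_frac see [match_lesions()].
#' @param scan_id optional scan identifier.
#' @return List with elements `match` ([match_lesions()] table) and `metrics`
#'   ([scan_metrics()] row).
#' @export
evaluate <- function(gt_mask, pred, size_threshold = 0,
                     lesion_code = CODE_LESION, connectivity = 26L,
                     min_overlap_frac = 0, scan_id = NA_character_) {
  gt_bin <- lesion_mask_from(gt_mask, lesion_code)
  pred_bin <- lesion_mask_from(pred, lesion_code)
  gt_comp <- extract_components(gt_bin, connectivity, source = "gt")
  pred_comp <- extract_components(pred_bin, connectivity, source = "pred")
  pred_comp <- filter_by_size(pred_comp, size_threshold)
  mt <- match_lesions(gt_comp, pred_comp,
                      min_overlap_frac = min_overlap_frac)
  list(match = mt,
       metrics = scan_metrics(mt, scan_id = scan_id),
       size_threshold = size_threshold)
}
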