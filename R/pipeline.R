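#' Desk-scale baseline segmenter
#'
#' A deliberately simple HU-window segmenter that makes the full pipeline
#' executable end to end on a workstation: the lesion class is every voxel
#' whose intensity falls inside `hu_window` and that lies inside the body,
#' minus any candidate component touching the body surface (which removes the
#' bright rim artifacts a pure threshold produces). Everything else inside
#' the body is the body class; outside is background. It is a baseline, not a
#' learned model; trained-segmenter predictions enter the pipeline as
#' external NIfTI masks instead.
#'
#' @param ct CT volume in HU.
#' @param body_mask aligned binary body mask.
#' @param hu_window `c(low, high)` lesion intensity window in HU.
#' @param connectivity component connectivity for the surface cleanup.
#' @return Integer label map with codes 0 (background), 1 (body), 2 (lesion).
#' @export
baseline_segment <- function(ct, body_mask, hu_window = c(55, 90),
                             connectivity = 26L) {
  body_mask <- as_mask(body_mask, "body_mask")
  dims <- check_dims3(ct, "ct")
  if (!any(body_mask))
    stop_weakbox("body mask is empty: nothing to segment",
                 class = "weakbox3d_empty_body_error")
  cand <- array(ct >= hu_window[1] & ct <= hu_window[2] & body_mask,
                dim = dims)
  if (any(cand)) {
    # body-surface voxels: body voxels 26-adjacent to a non-body voxel
    surface <- body_mask & .dilate_cpp(array(!body_mask, dim = dims), dims, 1L)
    labels <- .label_components_cpp(cand, dims, as.integer(connectivity))
    touching <- unique(labels[labels > 0L & surface])
    if (length(touching)) cand[array(labels %in% touching, dim = dims)] <- FALSE
  }
  merge_with_body(cand, body_mask)
}

#' Recorded external-tool adapter metadata
#'
#' The pipeline never trains or runs a deep segmentation model itself; it
#' consumes prediction masks from a directory. This function records, as
#' provenance metadata only, the training recipe associated with externally
#' produced nnU-Net predictions (3D full-resolution configuration, 5-fold
#' cross-validation, 1000 epochs, equally weighted binary cross-entropy +
#' soft Dice loss, SGD with initial learning rate 1e-3, batch size 1,
#' fold-ensembled inference) and a command template for producing a
#' body-region mask with TotalSegmentator. Nothing here is executed or
#' imported; no metric depends on these values.
#'
#' @return Nested list of adapter metadata.
#' @export
adapter_metadata <- function() {
  list(
    nnunet = list(
      configuration = "3d_fullres",
      folds = 5L, epochs = 1000L, batch_size = 1L,
      loss = "equally weighted binary cross-entropy + soft Dice",
      optimizer = "SGD", initial_lr = 1e-3,
      inference = "predictions from the five fold models ensembled",
      consumes = "per-scan NIfTI label maps in an external prediction directory"),
    totalsegmentator = list(
      command_template = "TotalSegmentator -i {ct.nii.gz} -o {out_dir} --body_seg",
      consumes = "any nonzero voxel of the output is treated as body"),
    display_window_hu = c(center = 50, width = 450))
}

#' Pipeline run configuration
#'
#' @param ct_dir directory of per-scan CT NIfTI files (`<scan_id>.nii.gz`).
#' @param boxes_csv cohort annotation CSV (see [read_boxes_csv()]).
#' @param out_dir run output directory.
#' @param radius weak-box slice-extension radius.
#' @param body_source `"auto"` for the HU-threshold fallback, or a directory
#'   of `<scan_id>.nii.gz` body masks.
#' @param segmenter `"baseline"`, or a directory of `<scan_id>.nii.gz`
#'   prediction masks produced externally.
#' @param hu_window baseline segmenter lesion HU window.
#' @param hu_threshold fallback body-segmentation threshold in HU.
#' @param size_threshold prediction voxel-size threshold for evaluation.
#' @param connectivity component connectivity.
#' @param lesion_code lesion class code in label maps.
#' @param seed run seed (recorded; the pipeline itself is deterministic).
#' @return An object of class `pipeline_config` (a fully serializable list).
#' @export
pipeline_config <- function(ct_dir, boxes_csv, out_dir, radius = 3L,
                            body_source = "auto", segmenter = "baseline",
                            hu_window = c(55, 90), hu_threshold = -500,
                            size_threshold = 250, connectivity = 26L,
                            lesion_code = 2L, seed = 1L) {
  structure(list(ct_dir = ct_dir, boxes_csv = boxes_csv, out_dir = out_dir,
                 radius = as.integer(radius), body_source = body_source,
                 segmenter = segmenter, hu_window = as.numeric(hu_window),
                 hu_threshold = hu_threshold,
                 size_threshold = size_threshold,
                 connectivity = as.integer(connectivity),
                 lesion_code = as.integer(lesion_code),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_weakbox("unknown config fields: %s", paste(unknown, collapse = ", "),
                 class = "weakbox3d_validation_error")
  do.call(pipeline_config, vals)
}

#' @noRd
summary_to_df <- function(cs) {
  p <- cs$pooled
  s <- cs$stats
  g <- function(metric, col) s[s$metric == metric, col]
  data.frame(
    statistic = c("pooled", "mean", "sd", "median", "q25", "q75",
                  "n_defined", "n_excluded"),
    tp = c(p$tp, rep(NA, 7)), fp = c(p$fp, rep(NA, 7)),
    fn = c(p$fn, rep(NA, 7)),
    precision = c(p$precision, g("precision", "mean"), g("precision", "sd"),
                  g("precision", "median"), g("precision", "q25"),
                  g("precision", "q75"), g("precision", "n_defined"),
                  g("precision", "n_excluded")),
    recall = c(p$recall, g("recall", "mean"), g("recall", "sd"),
               g("recall", "median"), g("recall", "q25"), g("recall", "q75"),
               g("recall", "n_defined"), g("recall", "n_excluded")))
}

#' Evaluate a cohort of scans from a file manifest
#'
#' Runs [evaluate()] per scan and aggregates with [cohort_summary()].
#'
#' @param manifest data.frame with columns `scan_id`, `gt_path`, `pred_path`
#'   (NIfTI files), or a CSV path with those columns.
#' @param size_threshold,lesion_code,connectivity see [evaluate()].
#' @param report optional path: writes the per-scan report CSV here and the
#'   summary next to it as `<report>_summary.csv`.
#' @return List with `per_scan` (data.frame of [scan_metrics()] rows) and
#'   `summary` ([cohort_summary()]).
#' @export
eval_cohort <- function(manifest, size_threshold = 0, lesion_code = 2L,
                        connectivity = 26L, report = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  stopifnot(all(c("scan_id", "gt_path", "pred_path") %in% names(manifest)))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    gt <- RNifti::readNifti(manifest$gt_path[i])
    pred <- RNifti::readNifti(manifest$pred_path[i])
    evaluate(array(as.vector(gt), dim = dim(gt)[1:3]),
             array(as.vector(pred), dim = dim(pred)[1:3]),
             size_threshold = size_threshold, lesion_code = lesion_code,
             connectivity = connectivity,
             scan_id = manifest$scan_id[i])$metrics
  })
  per_scan <- do.call(rbind, rows)
  cs <- cohort_summary(per_scan)
  if (!is.null(report)) {
    write.csv(per_scan, report, row.names = FALSE)
    write.csv(summary_to_df(cs),
              sub("(\\.csv)?$", "_summary.csv", report, perl = TRUE)[1],
              row.names = FALSE)
  }
  list(per_scan = per_scan, summary = cs)
}

#' @noRd
find_scans <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  data.frame(scan_id = vapply(paths, scan_id_from_path, ""), ct = paths,
             row.names = NULL)
}

#' Run the full pipeline over a cohort
#'
#' For every CT in the configured directory: obtain a body mask (external or
#' fallback), build the weak label map from this scan's 2D boxes, produce a
#' prediction (baseline segmenter or an externally supplied mask), and
#' evaluate the prediction against the weak labels. Writes label maps and
#' predictions as NIfTI, a per-scan report CSV, a cohort summary CSV, the
#' resolved configuration, and a log with per-stage wall times and voxel
#' counts. A failing stage aborts with the stage name and scan id; outputs
#' already written are retained.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @return The run directory path, invisibly; the per-scan report and summary
#'   are attached as attributes `"per_scan"` and `"summary"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(file.path(out, "labels"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "pred"), recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logf <- function(fmt, ...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%OS2"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("weakbox3d %s | R %s | seed %d",
       as.character(utils::packageVersion("weakbox3d")),
       paste(R.version$major, R.version$minor, sep = "."), config$seed)
  yaml::write_yaml(unclass(config), file.path(out, "config.yaml"))
  scans <- find_scans(config$ct_dir)
  if (nrow(scans) == 0L)
    stop_weakbox("no NIfTI volumes found in '%s'", config$ct_dir,
                 class = "weakbox3d_validation_error")
  boxes <- read_boxes_csv(config$boxes_csv)
  stage <- function(name, scan_id, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop_weakbox("stage '%s' failed for scan '%s': %s", name, scan_id,
                   conditionMessage(e), class = "weakbox3d_stage_error"))
    logf("%s | %s | %.2fs", scan_id, name, proc.time()[["elapsed"]] - t0)
    res
  }
  rows <- vector("list", nrow(scans))
  for (i in seq_len(nrow(scans))) {
    id <- scans$scan_id[i]
    ct_img <- RNifti::readNifti(scans$ct[i])
    ct <- array(as.vector(ct_img), dim = dim(ct_img)[1:3])
    body <- stage("body", id, {
      if (identical(config$body_source, "auto"))
        segment_body_fallback(ct, hu_threshold = config$hu_threshold)
      else load_body_mask(file.path(config$body_source,
                                    paste0(id, ".nii.gz")), reference = ct)
    })
    lm <- stage("make-labels", id,
                make_weak_labels(boxes, body, scan_id = id,
                                 radius = config$radius))
    gt_lesion <- attr(lm, "lesion_mask")
    attr(lm, "lesion_mask") <- NULL
    RNifti::writeNifti(RNifti::asNifti(lm, reference = ct_img),
                       file.path(out, "labels", paste0(id, ".nii.gz")))
    pred <- stage("segment", id, {
      if (identical(config$segmenter, "baseline"))
        baseline_segment(ct, body, hu_window = config$hu_window,
                         connectivity = config$connectivity)
      else {
        path <- file.path(config$segmenter, paste0(id, ".nii.gz"))
        if (!file.exists(path))
          stop(sprintf("no external prediction at '%s'", path))
        p <- RNifti::readNifti(path)
        array(as.vector(p), dim = dim(p)[1:3])
      }
    })
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(pred),
                                             dim = dim(pred)),
                                       reference = ct_img),
                       file.path(out, "pred", paste0(id, ".nii.gz")))
    ev <- stage("eval", id,
                evaluate(gt_lesion, pred,
                         size_threshold = config$size_threshold,
                         lesion_code = config$lesion_code,
                         connectivity = config$connectivity, scan_id = id))
    logf("%s | voxels: gt=%d pred=%d", id, sum(gt_lesion),
         sum(lesion_mask_from(pred, config$lesion_code)))
    rows[[i]] <- ev$metrics
  }
  per_scan <- do.call(rbind, rows)
  cs <- cohort_summary(per_scan)
  write.csv(per_scan, file.path(out, "report.csv"), row.names = FALSE)
  write.csv(summary_to_df(cs), file.path(out, "summary.csv"),
            row.names = FALSE)
  logf("done: %d scans, pooled TP=%d FP=%d FN=%d", nrow(per_scan),
       cs$pooled$tp, cs$pooled$fp, cs$pooled$fn)
  structure(invisible(out), per_scan = per_scan, summary = cs)
}
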