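#' Specification of a synthetic CT phantom
#'
#' Describes a CT-like volume: an ellipsoidal soft-tissue "body" in an air
#' background, containing ellipsoidal lesions of controllable size whose
#' intensities sit above the body tissue (an enhancing-tumor analog). The
#' default lesion semi-axis range (2–8 voxels) spans component volumes from a
#' few tens of voxels (well below a 250-voxel size threshold) to over two
#' thousand, emulating the wide size spread of real lesions. Identical spec +
#' seed yields bit-identical outputs.
#'
#' @param shape volume dimensions `c(rows, cols, slices)`.
#' @param body_semiaxes semi-axes of the body ellipsoid in voxels.
#' @param body_hu body tissue intensity in HU (soft tissue ~40).
#' @param background_hu air intensity (default -1000 HU).
#' @param n_lesions number of lesions to place.
#' @param lesion_semiaxes range `c(min, max)` each lesion semi-axis is drawn
#'   from, uniformly, in voxels.
#' @param lesion_hu range `c(min, max)` of lesion intensity in HU.
#' @param noise_sigma additive Gaussian noise standard deviation in HU.
#' @param seed random seed.
#' @param max_attempts rejection-sampling cap per lesion placement.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 64L),
                         body_semiaxes = c(38, 38, 28),
                         body_hu = 40, background_hu = -1000,
                         n_lesions = 5L,
                         lesion_semiaxes = c(2, 8),
                         lesion_hu = c(60, 90),
                         noise_sigma = 5, seed = 1L,
                         max_attempts = 1000L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(body_semiaxes) == 3L, all(body_semiaxes > 0),
            n_lesions >= 0L,
            length(lesion_semiaxes) == 2L,
            lesion_semiaxes[1] > 0, diff(lesion_semiaxes) >= 0,
            length(lesion_hu) == 2L, noise_sigma >= 0,
            max_attempts >= 1L)
  structure(list(shape = shape, body_semiaxes = body_semiaxes,
                 body_hu = body_hu, background_hu = background_hu,
                 n_lesions = as.integer(n_lesions),
                 lesion_semiaxes = lesion_semiaxes, lesion_hu = lesion_hu,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "phantom_spec")
}

# Logical mask of the ellipsoid with voxel-center membership
# ((i - center)/semiaxis)^2 summed <= 1; coordinates are 1-based voxel centers.
#' @noRd
ellipsoid_mask <- function(shape, center, semiaxes) {
  u2 <- ((seq_len(shape[1]) - center[1]) / semiaxes[1])^2
  v2 <- ((seq_len(shape[2]) - center[2]) / semiaxes[2])^2
  w2 <- ((seq_len(shape[3]) - center[3]) / semiaxes[3])^2
  d <- outer(outer(u2, v2, `+`), w2, `+`)
  d <= 1
}

#' Generate a synthetic CT phantom with ground-truth lesions
#'
#' Builds the CT volume (background + body + lesions + Gaussian noise), the
#' ground-truth lesion mask, and per-lesion component records. Lesions are
#' placed by rejection sampling fully inside the body with a safety margin
#' from its surface, pairwise disjoint with at least a one-voxel gap (so each
#' lesion is its own 26-connected component). Placement failure after the
#' attempt cap is an error, never a silent undercount.
#'
#' @param spec a [phantom_spec()].
#' @return List with `ct` (numeric HU array), `gt` (logical lesion mask),
#'   `body` (logical body mask), `lesions` (data.frame of per-lesion records)
#'   and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    dims <- spec$shape
    center <- (dims + 1) / 2
    body <- ellipsoid_mask(dims, center, spec$body_semiaxes)
    # 2-voxel interior margin keeps lesions off the body surface
    interior <- .erode_cpp(body, dims, 2L)
    ct <- array(spec$background_hu, dim = dims)
    ct[body] <- spec$body_hu
    gt <- array(FALSE, dim = dims)
    occupied <- array(FALSE, dim = dims)  # gt dilated by 1: enforces gaps
    rec <- vector("list", spec$n_lesions)
    for (i in seq_len(spec$n_lesions)) {
      placed <- FALSE
      for (att in seq_len(spec$max_attempts)) {
        ax <- runif(3, spec$lesion_semiaxes[1], spec$lesion_semiaxes[2])
        ctr <- c(runif(1, 1 + ax[1], dims[1] - ax[1]),
                 runif(1, 1 + ax[2], dims[2] - ax[2]),
                 runif(1, 1 + ax[3], dims[3] - ax[3]))
        les <- ellipsoid_mask(dims, ctr, ax)
        if (!any(les)) next
        if (!all(interior[les])) next
        if (any(occupied[les])) next
        hu <- runif(1, spec$lesion_hu[1], spec$lesion_hu[2])
        ct[les] <- hu
        gt <- gt | les
        occupied <- occupied | .dilate_cpp(les, dims, 1L)
        rec[[i]] <- data.frame(id = i, voxels = sum(les),
                               centroid_row = ctr[1], centroid_col = ctr[2],
                               centroid_z = ctr[3],
                               semi_row = ax[1], semi_col = ax[2],
                               semi_z = ax[3], hu = hu)
        placed <- TRUE
        break
      }
      if (!placed)
        stop_weakbox("could not place lesion %d of %d after %d attempts; use fewer or smaller lesions or a larger body",
                     i, spec$n_lesions, spec$max_attempts,
                     class = "weakbox3d_placement_error")
    }
    if (spec$noise_sigma > 0)
      ct <- ct + array(rnorm(prod(dims), 0, spec$noise_sigma), dim = dims)
    lesions <- if (spec$n_lesions > 0) do.call(rbind, rec) else
      data.frame(id = integer(), voxels = integer(),
                 centroid_row = numeric(), centroid_col = numeric(),
                 centroid_z = numeric(), semi_row = numeric(),
                 semi_col = numeric(), semi_z = numeric(), hu = numeric())
    list(ct = ct, gt = gt, body = body, lesions = lesions, spec = spec)
  })
}

#' Derive per-lesion 2D maximum-area boxes from a ground-truth mask
#'
#' Automated analog of the annotator's action: for each 3D lesion component,
#' pick the axial slice where the component shows its largest in-plane area
#' (ties broken toward the smallest slice index) and return the tight in-plane
#' bounding box on that slice as a [box2d()].
#'
#' @param gt_mask binary lesion mask.
#' @param scan_id scan identifier stamped on each box.
#' @param connectivity component connectivity (default 26).
#' @return List of [box2d()] objects, one per component, in component order.
#' @export
derive_2d_boxes <- function(gt_mask, scan_id = "phantom",
                            connectivity = 26L) {
  comp <- extract_components(gt_mask, connectivity)
  labels <- attr(comp, "labels")
  dims <- dim(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  coord <- arrayInd(idx, dims)
  lapply(comp$id, function(id) {
    sel <- lab == id
    zs <- coord[sel, 3]
    area <- tabulate(zs, nbins = dims[3])
    z_best <- which.max(area)  # which.max takes the first (smallest z) tie
    on_slice <- sel & coord[, 3] == z_best
    rows <- coord[on_slice, 1]
    cols <- coord[on_slice, 2]
    box2d(scan_id, z = z_best - 1L,
          row_min = min(rows) - 1L, col_min = min(cols) - 1L,
          row_max = max(rows), col_max = max(cols))
  })
}

#' Specification of a controlled prediction degradation
#'
#' Turns a ground-truth mask into a realistic "model prediction" with known
#' error counts: drop `n_drop` true components (false negatives), inject
#' `n_inject` spurious ellipsoidal blobs placed disjoint from everything
#' (false positives), and jitter each surviving component's boundary by a
#' random dilation/erosion radius in `[-jitter, jitter]`.
#'
#' @param n_drop number of ground-truth components to remove.
#' @param n_inject number of spurious blobs to add.
#' @param inject_semiaxes range `c(min, max)` of blob semi-axes in voxels.
#' @param jitter maximum dilation/erosion radius per surviving component.
#' @param seed random seed.
#' @param max_attempts rejection-sampling cap per blob placement.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(n_drop = 0L, n_inject = 0L,
                             inject_semiaxes = c(1.5, 4), jitter = 0L,
                             seed = 1L, max_attempts = 1000L) {
  stopifnot(n_drop >= 0L, n_inject >= 0L,
            length(inject_semiaxes) == 2L, inject_semiaxes[1] > 0,
            diff(inject_semiaxes) >= 0, jitter >= 0L, max_attempts >= 1L)
  structure(list(n_drop = as.integer(n_drop), n_inject = as.integer(n_inject),
                 inject_semiaxes = inject_semiaxes,
                 jitter = as.integer(jitter), seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "degradation_spec")
}

#' Degrade a ground-truth mask into a synthetic prediction
#'
#' Applies a [degradation_spec()]: the output equals the ground truth minus
#' the dropped components, plus the injected blobs, with per-component
#' morphological jitter. The construction guarantees the evaluation protocol
#' recovers the degradation exactly: every surviving component still overlaps
#' its source lesion and nothing else, every injected blob (kept at least one
#' voxel away from all other structures) is a distinct unmatched component,
#' and dropped lesions overlap nothing.
#'
#' @param gt_mask binary ground-truth lesion mask.
#' @param spec a [degradation_spec()].
#' @param connectivity component connectivity (default 26).
#' @return Logical prediction mask with attributes `dropped_ids` (ids in the
#'   ground-truth component labeling), `n_injected`, and `injected`
#'   (data.frame of blob records).
#' @export
degrade_prediction <- function(gt_mask, spec, connectivity = 26L) {
  stopifnot(inherits(spec, "degradation_spec"))
  gt_mask <- as_mask(gt_mask, "gt_mask")
  dims <- check_dims3(gt_mask)
  comp <- extract_components(gt_mask, connectivity)
  if (spec$n_drop > nrow(comp))
    stop_weakbox("cannot drop %d of %d ground-truth components",
                 spec$n_drop, nrow(comp),
                 class = "weakbox3d_validation_error")
  labels <- attr(comp, "labels")
  with_seed(spec$seed, {
    dropped <- if (spec$n_drop > 0)
      sort(sample(comp$id, spec$n_drop)) else integer()
    kept <- setdiff(comp$id, dropped)
    pred <- array(FALSE, dim = dims)
    for (id in kept) {
      base <- array(labels == id, dim = dims)
      r <- if (spec$jitter > 0)
        sample(seq(-spec$jitter, spec$jitter), 1L) else 0L
      if (r > 0) {
        grown <- .dilate_cpp(base, dims, r)
        # growth may not reach other GT lesions (would match them) nor come
        # within one voxel of already-built prediction components (would merge)
        forbidden <- .dilate_cpp(array(gt_mask & !base, dim = dims), dims, 1L) |
          .dilate_cpp(pred, dims, 1L)
        grown <- grown & !forbidden
        grown <- grown | base  # the source voxels always survive
        pred <- pred | grown
      } else if (r < 0) {
        shr <- .erode_cpp(base, dims, -r)
        if (!any(shr)) {
          # erosion annihilated a small component: keep its most interior voxel
          ctr <- c(comp$centroid_row[comp$id == id],
                   comp$centroid_col[comp$id == id],
                   comp$centroid_z[comp$id == id])
          vox <- arrayInd(which(base), dims)
          d2 <- (vox[, 1] - ctr[1])^2 + (vox[, 2] - ctr[2])^2 +
            (vox[, 3] - ctr[3])^2
          shr[which(base)[which.min(d2)]] <- TRUE
        }
        pred <- pred | shr
      } else {
        pred <- pred | base
      }
    }
    injected <- vector("list", spec$n_inject)
    forbidden <- .dilate_cpp(array(gt_mask | pred, dim = dims), dims, 1L)
    for (j in seq_len(spec$n_inject)) {
      ok <- FALSE
      for (att in seq_len(spec$max_attempts)) {
        ax <- runif(3, spec$inject_semiaxes[1], spec$inject_semiaxes[2])
        ctr <- c(runif(1, 1 + ax[1], dims[1] - ax[1]),
                 runif(1, 1 + ax[2], dims[2] - ax[2]),
                 runif(1, 1 + ax[3], dims[3] - ax[3]))
        blob <- ellipsoid_mask(dims, ctr, ax)
        if (!any(blob) || any(forbidden[blob])) next
        pred <- pred | blob
        forbidden <- forbidden | .dilate_cpp(blob, dims, 1L)
        injected[[j]] <- data.frame(blob = j, voxels = sum(blob),
                                    centroid_row = ctr[1],
                                    centroid_col = ctr[2],
                                    centroid_z = ctr[3])
        ok <- TRUE
        break
      }
      if (!ok)
        stop_weakbox("could not place spurious blob %d of %d disjoint from existing structures after %d attempts",
                     j, spec$n_inject, spec$max_attempts,
                     class = "weakbox3d_placement_error")
    }
    attr(pred, "dropped_ids") <- dropped
    attr(pred, "n_injected") <- spec$n_inject
    attr(pred, "injected") <- if (spec$n_inject > 0) do.call(rbind, injected)
      else data.frame(blob = integer(), voxels = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      centroid_z = numeric())
    pred
  })
}

#' Write a phantom scan to disk as pipeline-ready files
#'
#' Writes `"<scan_id>_ct.nii.gz"`, `"<scan_id>_gt.nii.gz"`, appends the
#' derived 2D boxes to a cohort `boxes.csv`, and records the spec and lesion
#' truth in `"<scan_id>_truth.json"`.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @param scan_id scan identifier used in file names.
#' @return Named list of written paths, invisibly.
#' @export
write_phantom <- function(spec, out_dir, scan_id = "phantom") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- generate_phantom(spec)
  ct_path <- file.path(out_dir, paste0(scan_id, "_ct.nii.gz"))
  gt_path <- file.path(out_dir, paste0(scan_id, "_gt.nii.gz"))
  truth_path <- file.path(out_dir, paste0(scan_id, "_truth.json"))
  boxes_path <- file.path(out_dir, "boxes.csv")
  RNifti::writeNifti(RNifti::asNifti(ph$ct), ct_path)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(ph$gt),
                                           dim = dim(ph$gt))), gt_path)
  boxes <- derive_2d_boxes(ph$gt, scan_id = scan_id)
  if (file.exists(boxes_path)) {
    existing <- read_boxes_csv(boxes_path)
    existing <- Filter(function(b) b$scan_id != scan_id, existing)
    boxes <- c(existing, boxes)
  }
  write_boxes_csv(boxes, boxes_path)
  jsonlite::write_json(list(scan_id = scan_id, spec = unclass(ph$spec),
                            lesions = ph$lesions),
                       truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(ct = ct_path, gt = gt_path, boxes = boxes_path,
                 truth = truth_path))
}
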