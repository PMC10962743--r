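#' Single-slice 2D box annotation
#'
#' The prospective RECIST-style mark: a rectangle drawn around a lesion on the
#' one axial slice where it shows its maximum diameter. Coordinates follow the
#' annotation-file convention: 0-based indices, half-open intervals, so a box
#' with `row_min = 10, row_max = 14` covers rows 10, 11, 12, 13 (4 rows) and
#' `z` is the 0-based axial slice index. Annotators counting 1-based must
#' subtract one when exporting.
#'
#' @param scan_id character scan identifier.
#' @param z 0-based axial slice index of the annotated slice.
#' @param row_min,col_min inclusive 0-based in-plane start indices.
#' @param row_max,col_max exclusive in-plane end indices.
#' @return An object of class `box2d`.
#' @export
#' @examples
#' box2d("scan01", z = 10, row_min = 4, col_min = 6, row_max = 9, col_max = 12)
box2d <- function(scan_id, z, row_min, col_min, row_max, col_max) {
  z <- as.integer(z)
  row_min <- as.integer(row_min); row_max <- as.integer(row_max)
  col_min <- as.integer(col_min); col_max <- as.integer(col_max)
  if (is.na(z) || z < 0L)
    stop_weakbox("box for scan '%s': slice index z must be a non-negative integer",
                 scan_id, class = "weakbox3d_validation_error")
  if (row_min >= row_max || col_min >= col_max)
    stop_weakbox("box for scan '%s' at z=%d: degenerate extent (require row_min < row_max and col_min < col_max)",
                 scan_id, z, class = "weakbox3d_validation_error")
  if (row_min < 0L || col_min < 0L)
    stop_weakbox("box for scan '%s' at z=%d: negative in-plane start index",
                 scan_id, z, class = "weakbox3d_validation_error")
  structure(list(scan_id = as.character(scan_id), z = z,
                 row_min = row_min, col_min = col_min,
                 row_max = row_max, col_max = col_max),
            class = "box2d")
}

#' @export
print.box2d <- function(x, ...) {
  cat(sprintf("<box2d> scan %s, slice z=%d, rows [%d,%d), cols [%d,%d)\n",
              x$scan_id, x$z, x$row_min, x$row_max, x$col_min, x$col_max))
  invisible(x)
}

#' Extend a 2D box annotation into a weak 3D box
#'
#' Copies the in-plane rectangle onto the `radius` adjacent slices above and
#' below the annotated slice, clipped at the volume ends. With the default
#' `radius = 3` an interior annotation yields a 7-slice box; near the first or
#' last slice the box is clipped rather than rejected so edge annotations stay
#' usable.
#'
#' @param box a [box2d()].
#' @param n_slices number of axial slices in the referenced volume.
#' @param radius number of slices added on each side (default 3).
#' @return An object of class `weak_box3d`: the box2d fields plus `z_min`
#'   (inclusive), `z_max` (exclusive) and `source_z`, all 0-based.
#' @export
#' @examples
#' b <- box2d("s", z = 10, row_min = 0, col_min = 0, row_max = 5, col_max = 5)
#' w <- extend_box_to_3d(b, n_slices = 40)
#' w$z_max - w$z_min  # 7 slices
extend_box_to_3d <- function(box, n_slices, radius = 3L) {
  stopifnot(inherits(box, "box2d"))
  n_slices <- as.integer(n_slices)
  radius <- as.integer(radius)
  if (n_slices < 1L || radius < 0L)
    stop_weakbox("need n_slices >= 1 and radius >= 0",
                 class = "weakbox3d_validation_error")
  if (box$z >= n_slices)
    stop_weakbox("annotation for scan '%s' references slice z=%d but the volume has only %d slices",
                 box$scan_id, box$z, n_slices,
                 class = "weakbox3d_annotation_error")
  out <- unclass(box)
  out$z_min <- max(0L, box$z - radius)
  out$z_max <- min(n_slices, box$z + radius + 1L)
  out$source_z <- box$z
  out$z <- NULL
  structure(out, class = c("weak_box3d"))
}

#' @export
print.weak_box3d <- function(x, ...) {
  cat(sprintf("<weak_box3d> scan %s, slices [%d,%d) from z=%d, rows [%d,%d), cols [%d,%d)\n",
              x$scan_id, x$z_min, x$z_max, x$source_z,
              x$row_min, x$row_max, x$col_min, x$col_max))
  invisible(x)
}

#' Rasterize weak 3D boxes into a binary lesion mask
#'
#' A voxel is foreground iff it lies inside at least one box; overlapping
#' boxes merge without double counting.
#'
#' @param boxes list of [extend_box_to_3d()] results (a single box is also
#'   accepted).
#' @param shape integer vector `c(rows, cols, slices)`.
#' @return Logical array of dimension `shape`.
#' @export
rasterize_weak_boxes <- function(boxes, shape) {
  if (inherits(boxes, "weak_box3d")) boxes <- list(boxes)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  mask <- array(FALSE, dim = shape)
  for (b in boxes) {
    stopifnot(inherits(b, "weak_box3d"))
    if (b$row_max > shape[1] || b$col_max > shape[2] || b$z_max > shape[3] ||
        b$z_min < 0L)
      stop_weakbox("box for scan '%s' (rows [%d,%d), cols [%d,%d), slices [%d,%d)) exceeds volume shape %s",
                   b$scan_id, b$row_min, b$row_max, b$col_min, b$col_max,
                   b$z_min, b$z_max, paste(shape, collapse = "x"),
                   class = "weakbox3d_bounds_error")
    mask[(b$row_min + 1L):b$row_max,
         (b$col_min + 1L):b$col_max,
         (b$z_min + 1L):b$z_max] <- TRUE
  }
  mask
}

#' Merge a lesion mask with a body mask into a training label map
#'
#' Produces the integer-coded label map used to train a segmenter: 0 =
#' background (air), 1 = body, 2 = lesion. The lesion class wins every
#' conflict, so a weak box spilling outside the body keeps code 2 there.
#'
#' @param lesion_mask binary lesion mask.
#' @param body_mask binary body mask of the same shape.
#' @return Integer array with codes \{0, 1, 2\}.
#' @export
merge_with_body <- function(lesion_mask, body_mask) {
  lesion_mask <- as_mask(lesion_mask, "lesion_mask")
  body_mask <- as_mask(body_mask, "body_mask")
  if (!identical(dim(lesion_mask), dim(body_mask)))
    stop_weakbox("lesion mask shape (%s) does not match body mask shape (%s)",
                 paste(dim(lesion_mask), collapse = "x"),
                 paste(dim(body_mask), collapse = "x"),
                 class = "weakbox3d_structure_error")
  out <- array(CODE_BACKGROUND, dim = dim(lesion_mask))
  out[body_mask] <- CODE_BODY
  out[lesion_mask] <- CODE_LESION
  storage.mode(out) <- "integer"
  out
}

#' Read 2D box annotations from CSV
#'
#' Expects header `scan_id,z,row_min,col_min,row_max,col_max`, one row per 2D
#' box, UTF-8, comma-separated. All coordinates 0-based; `row_max`/`col_max`
#' exclusive.
#'
#' @param path CSV file path.
#' @return List of [box2d()] objects.
#' @export
read_boxes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("scan_id", "z", "row_min", "col_min", "row_max", "col_max")
  if (!all(needed %in% names(df)))
    stop_weakbox("annotation CSV '%s' must have columns %s", path,
                 paste(needed, collapse = ","),
                 class = "weakbox3d_validation_error")
  lapply(seq_len(nrow(df)), function(i)
    box2d(df$scan_id[i], df$z[i], df$row_min[i], df$col_min[i],
          df$row_max[i], df$col_max[i]))
}

#' Write 2D box annotations to CSV
#'
#' @param boxes list of [box2d()] objects.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_boxes_csv <- function(boxes, path) {
  df <- do.call(rbind, lapply(boxes, function(b)
    data.frame(scan_id = b$scan_id, z = b$z, row_min = b$row_min,
               col_min = b$col_min, row_max = b$row_max, col_max = b$col_max)))
  if (is.null(df))
    df <- data.frame(scan_id = character(), z = integer(),
                     row_min = integer(), col_min = integer(),
                     row_max = integer(), col_max = integer())
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a weak training label map for one scan
#'
#' End-to-end label construction for a single CT: select this scan's boxes,
#' extend each to a 7-slice weak 3D box, rasterize, and merge with the body
#' mask. File-based wrapper: see [make_weak_labels_nifti()].
#'
#' @param boxes list of [box2d()] (boxes for other `scan_id`s are ignored when
#'   `scan_id` is given).
#' @param body_mask binary body mask defining the volume shape.
#' @param scan_id scan whose boxes to use, or `NULL` for all boxes.
#' @param radius slice-extension radius (default 3).
#' @return Integer label map (codes 0/1/2) with the lesion mask as attribute
#'   `"lesion_mask"`.
#' @export
make_weak_labels <- function(boxes, body_mask, scan_id = NULL, radius = 3L) {
  body_mask <- as_mask(body_mask, "body_mask")
  shape <- check_dims3(body_mask, "body_mask")
  if (!is.null(scan_id))
    boxes <- Filter(function(b) b$scan_id == scan_id, boxes)
  wboxes <- lapply(boxes, extend_box_to_3d, n_slices = shape[3],
                   radius = radius)
  lesion <- rasterize_weak_boxes(wboxes, shape)
  lm <- merge_with_body(lesion, body_mask)
  attr(lm, "lesion_mask") <- lesion
  lm
}

#' File-based weak label construction (NIfTI in, NIfTI out)
#'
#' Reads the CT (for geometry), the annotation CSV, and a body mask (external
#' NIfTI file or `"auto"` for the built-in HU-threshold fallback), writes the
#' merged label map as NIfTI preserving the CT affine and header geometry.
#'
#' @param ct_path CT NIfTI path.
#' @param boxes_path annotation CSV path (see [read_boxes_csv()]).
#' @param out_path output label-map NIfTI path.
#' @param body body mask NIfTI path, or `"auto"` to use
#'   [segment_body_fallback()].
#' @param scan_id scan id to select from the CSV; defaults to the CT file name
#'   without extensions.
#' @param radius slice-extension radius (default 3).
#' @param hu_threshold HU threshold for the fallback body mask.
#' @return `out_path`, invisibly.
#' @export
make_weak_labels_nifti <- function(ct_path, boxes_path, out_path,
                                   body = "auto", scan_id = NULL,
                                   radius = 3L, hu_threshold = -500) {
  ct <- RNifti::readNifti(ct_path)
  if (is.null(scan_id)) scan_id <- scan_id_from_path(ct_path)
  body_mask <- if (identical(body, "auto"))
    segment_body_fallback(ct, hu_threshold = hu_threshold)
  else load_body_mask(body, reference = ct)
  boxes <- read_boxes_csv(boxes_path)
  lm <- make_weak_labels(boxes, body_mask, scan_id = scan_id, radius = radius)
  attr(lm, "lesion_mask") <- NULL
  RNifti::writeNifti(RNifti::asNifti(lm, reference = ct), out_path)
  invisible(out_path)
}

#' @noRd
scan_id_from_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", basename(path))
}
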