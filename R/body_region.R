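#' Load an externally produced body mask
#'
#' Any nonzero voxel becomes foreground, so multi-organ label maps (e.g. a
#' whole-body segmentation tool's output) work unchanged as a body-vs-air
#' mask.
#'
#' @param path NIfTI mask path, or an already-loaded array.
#' @param reference optional CT array/image the mask must align with; a grid
#'   mismatch is an error naming both shapes.
#' @return Logical body mask with attribute `provenance = "external-file"`.
#' @export
load_body_mask <- function(path, reference = NULL) {
  img <- if (is.character(path)) RNifti::readNifti(path) else path
  check_dims3(img, "body mask")
  if (!is.null(reference) && !identical(dim(img)[1:3], dim(reference)[1:3]))
    stop_weakbox("body mask grid (%s) does not match CT grid (%s)",
                 paste(dim(img), collapse = "x"),
                 paste(dim(reference), collapse = "x"),
                 class = "weakbox3d_structure_error")
  mask <- array(as.vector(img) != 0, dim = dim(img)[1:3])
  if (!any(mask))
    warning("body mask is empty (no nonzero voxels)")
  attr(mask, "provenance") <- "external-file"
  mask
}

#' Built-in HU-threshold body segmentation
#'
#' Fallback body-region segmenter so the pipeline has no hard external
#' dependency: threshold the CT at `hu_threshold` (default -500 HU, between
#' air at about -1000 and soft tissue at 20-80), keep the largest 26-connected
#' component, then fill internal holes slice-wise so low-density interior
#' structures (lung analogs) stay inside the body.
#'
#' @param ct CT volume in Hounsfield units (3D array).
#' @param hu_threshold threshold above which a voxel is candidate body.
#' @return Logical body mask with attribute `provenance = "fallback"`.
#' @export
segment_body_fallback <- function(ct, hu_threshold = -500) {
  dims <- check_dims3(ct, "ct")
  cand <- array(as.vector(ct) > hu_threshold, dim = dims)
  if (!any(cand))
    stop_weakbox("no voxel above %g HU: cannot segment a body region",
                 hu_threshold, class = "weakbox3d_empty_body_error")
  labels <- .label_components_cpp(cand, dims, 26L)
  sizes <- tabulate(labels[labels > 0L], nbins = attr(labels, "n_components"))
  keep <- which.max(sizes)
  mask <- array(labels == keep, dim = dims)
  mask <- .fill_holes_slicewise_cpp(mask, dims)
  attr(mask, "provenance") <- "fallback"
  mask
}
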