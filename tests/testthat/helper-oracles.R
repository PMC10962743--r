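# Independent oracles, written in plain R so they share no code with the
# implementation they check.

# Neighborhood offsets for 6/18/26 connectivity.
oracle_offsets <- function(connectivity) {
  g <- expand.grid(dr = -1:1, dc = -1:1, dz = -1:1)
  m <- abs(g$dr) + abs(g$dc) + abs(g$dz)
  lim <- c(`6` = 1, `18` = 2, `26` = 3)[[as.character(connectivity)]]
  as.matrix(g[m >= 1 & m <= lim, ])
}

# Connected-component labeling by BFS flood fill from each unvisited seed.
oracle_flood_fill <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  off <- oracle_offsets(connectivity)
  labels <- array(0L, dim = dims)
  nxt <- 0L
  for (seed in which(mask)) {
    if (labels[seed] != 0L) next
    nxt <- nxt + 1L
    queue <- seed
    labels[seed] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      p <- arrayInd(v, dims)
      for (k in seq_len(nrow(off))) {
        q <- p + off[k, ]
        if (any(q < 1) || any(q > dims)) next
        w <- q[1] + (q[2] - 1) * dims[1] + (q[3] - 1) * dims[1] * dims[2]
        if (mask[w] && labels[w] == 0L) {
          labels[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

# Exhaustive pairwise-overlap detection matcher: for every (gt, pred)
# component pair, intersect their voxel index sets directly.
oracle_match <- function(gt_mask, pred_mask, connectivity = 26) {
  gl <- oracle_flood_fill(gt_mask, connectivity)
  pl <- oracle_flood_fill(pred_mask, connectivity)
  gt_ids <- setdiff(unique(as.vector(gl)), 0L)
  pred_ids <- setdiff(unique(as.vector(pl)), 0L)
  gt_matched <- logical(length(gt_ids))
  pred_matched <- logical(length(pred_ids))
  for (i in seq_along(gt_ids))
    for (j in seq_along(pred_ids)) {
      if (length(intersect(which(gl == gt_ids[i]),
                           which(pl == pred_ids[j]))) > 0) {
        gt_matched[i] <- TRUE
        pred_matched[j] <- TRUE
      }
    }
  list(tp = sum(gt_matched), fn = sum(!gt_matched),
       fp = sum(!pred_matched),
       n_gt = length(gt_ids), n_pred = length(pred_ids))
}

# Random blobby binary mask: seeds a few voxels and thickens them.
random_mask <- function(dims, n_seeds = 4, p_grow = 0.5) {
  mask <- array(FALSE, dim = dims)
  mask[sample(prod(dims), n_seeds)] <- TRUE
  grown <- weakbox3d:::.dilate_cpp(mask, as.integer(dims), 1L)
  extra <- grown & array(runif(prod(dims)) < p_grow, dim = dims)
  mask | extra
}

# Brute-force voxel membership test of a point-in-any-box raster.
oracle_box_raster <- function(boxes, shape) {
  mask <- array(FALSE, dim = shape)
  for (r in seq_len(shape[1]))
    for (c in seq_len(shape[2]))
      for (z in seq_len(shape[3]))
        for (b in boxes) {
          inside <- (r - 1) >= b$row_min && (r - 1) < b$row_max &&
            (c - 1) >= b$col_min && (c - 1) < b$col_max &&
            (z - 1) >= b$z_min && (z - 1) < b$z_max
          if (inside) mask[r, c, z] <- TRUE
        }
  mask
}

# Small fast phantom used across tests.
small_phantom_spec <- function(seed, n_lesions = 4,
                               shape = c(48L, 48L, 40L)) {
  phantom_spec(shape = shape, body_semiaxes = c(20, 20, 17),
               n_lesions = n_lesions, lesion_semiaxes = c(1.8, 5),
               seed = seed)
}
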