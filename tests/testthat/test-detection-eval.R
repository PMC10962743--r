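test_that("component extraction matches a flood-fill oracle on random masks", {
  set.seed(41)
  for (rep in 1:12) {
    dims <- c(15L, 15L, 15L)
    mask <- random_mask(dims, n_seeds = sample(2:6, 1))
    for (conn in c(6L, 26L)) {
      comp <- extract_components(mask, conn)
      oracle <- oracle_flood_fill(mask, conn)
      expect_equal(nrow(comp), max(oracle))
      expect_equal(sort(comp$voxels),
                   sort(as.integer(table(oracle[oracle > 0]))))
      # label partitions agree up to renaming
      labels <- attr(comp, "labels")
      expect_equal(sum(labels > 0), sum(mask))
      agree <- table(labels[labels > 0], oracle[oracle > 0])
      expect_equal(sum(agree > 0), max(oracle))
    }
  }
})

test_that("connectivity semantics: diagonal contact splits at 6, joins at 26", {
  mask <- array(FALSE, c(5, 5, 3))
  mask[2, 2, 2] <- TRUE
  mask[3, 3, 2] <- TRUE
  expect_equal(nrow(extract_components(mask, 26)), 1)
  expect_equal(nrow(extract_components(mask, 6)), 2)
  expect_equal(nrow(extract_components(array(FALSE, c(4, 4, 4)))), 0)
  expect_error(extract_components(array(2, c(3, 3, 3))),
               class = "weakbox3d_validation_error")
})

test_that("size filter keeps strictly larger components and preserves order", {
  comp <- data.frame(id = 1:3, voxels = c(100, 300, 500))
  expect_equal(filter_by_size(comp, 250)$voxels, c(300, 500))
  expect_equal(filter_by_size(comp, 0)$voxels, c(100, 300, 500))
  expect_equal(nrow(filter_by_size(comp, 500)), 0)   # boundary is exclusive
  expect_equal(filter_by_size(comp, 99)$id, 1:3)
})

test_that("percentile threshold interpolates order statistics", {
  sizes <- seq(10, 100, by = 10)
  expect_equal(percentile_size_threshold(sizes, 15), 23.5)
  expect_equal(percentile_size_threshold(sizes, 0), 10)
  expect_equal(percentile_size_threshold(sizes, 100), 100)
  expect_equal(percentile_size_threshold(rep(7, 5), 62), 7)
  expect_error(percentile_size_threshold(numeric(0)),
               class = "weakbox3d_insufficient_data_error")
})

test_that("lesion matching equals the exhaustive pairwise-overlap oracle", {
  set.seed(57)
  for (rep in 1:20) {
    dims <- c(12L, 12L, 12L)
    gt <- random_mask(dims, n_seeds = sample(1:4, 1))
    pred <- random_mask(dims, n_seeds = sample(1:4, 1))
    mt <- match_lesions(gt, pred)
    or <- oracle_match(gt, pred)
    expect_equal(mt$tp, or$tp)
    expect_equal(mt$fp, or$fp)
    expect_equal(mt$fn, or$fn)
    expect_equal(mt$tp + mt$fn, or$n_gt)   # conservation
  }
})

test_that("matching conventions: identity, disjoint, one-to-many", {
  dims <- c(20L, 20L, 10L)
  gt <- array(FALSE, dims)
  gt[2:5, 2:5, 2:4] <- TRUE
  gt[10:13, 10:13, 5:7] <- TRUE
  mt <- match_lesions(gt, gt)
  expect_equal(c(mt$tp, mt$fp, mt$fn), c(2, 0, 0))

  pred <- array(FALSE, dims)
  pred[15:18, 2:5, 2:4] <- TRUE
  mt2 <- match_lesions(gt, pred)
  expect_equal(c(mt2$tp, mt2$fp, mt2$fn), c(0, 1, 2))

  # one big prediction covering both GT lesions: two TPs, no FP
  blanket <- array(FALSE, dims)
  blanket[1:14, 1:14, 1:8] <- TRUE
  mt3 <- match_lesions(gt, blanket)
  expect_equal(c(mt3$tp, mt3$fp, mt3$fn), c(2, 0, 0))

  # two predictions on one GT lesion: one TP, no FPs
  twins <- array(FALSE, dims)
  twins[2:3, 2:5, 2:4] <- TRUE
  twins[5, 2:5, 2:4] <- TRUE   # gap at row 4 splits them
  single <- array(FALSE, dims)
  single[2:5, 2:5, 2:4] <- TRUE
  mt4 <- match_lesions(single, twins)
  expect_equal(c(mt4$tp, mt4$fp, mt4$fn), c(1, 0, 0))

  expect_error(match_lesions(gt, array(TRUE, c(5, 5, 5))),
               class = "weakbox3d_structure_error")
})

test_that("minimum-overlap fraction knob tightens the match criterion", {
  dims <- c(10L, 10L, 6L)
  gt <- array(FALSE, dims); gt[2:5, 2:5, 2:4] <- TRUE    # 48 voxels
  pred <- array(FALSE, dims); pred[5, 5, 4] <- TRUE      # 1 voxel overlap
  expect_equal(match_lesions(gt, pred)$tp, 1)
  mt <- match_lesions(gt, pred, min_overlap_frac = 0.5)
  expect_equal(c(mt$tp, mt$fp, mt$fn), c(0, 1, 1))
})

test_that("scan metrics reproduce ratios and flag undefined denominators", {
  m <- scan_metrics(tp = 98, fp = 59, fn = 55)
  expect_equal(m$precision, 98 / 157)
  expect_equal(m$recall, 98 / 153)
  expect_equal(m$n_gt, 153)

  empty_pred <- scan_metrics(tp = 0, fp = 0, fn = 5)
  expect_true(is.na(empty_pred$precision))
  expect_equal(empty_pred$recall, 0)

  no_gt <- scan_metrics(tp = 0, fp = 3, fn = 0)
  expect_true(is.na(no_gt$recall))
  expect_equal(no_gt$precision, 0)

  # fully empty scan scores perfect by convention
  expect_equal(scan_metrics(tp = 0, fp = 0, fn = 0)$precision, 1)
  expect_equal(scan_metrics(tp = 0, fp = 0, fn = 0)$recall, 1)
})

test_that("cohort summary pools counts and summarizes defined scans", {
  per_scan <- rbind(scan_metrics(tp = 1, fp = 1, fn = 0, scan_id = "a"),
                    scan_metrics(tp = 2, fp = 0, fn = 1, scan_id = "b"),
                    scan_metrics(tp = 3, fp = 0, fn = 0, scan_id = "c"))
  cs <- cohort_summary(per_scan)
  expect_equal(cs$pooled$tp, 6)
  expect_equal(cs$pooled$precision, 6 / 7)
  p <- cs$stats[cs$stats$metric == "precision", ]
  expect_equal(p$median, 1.0)
  expect_equal(p$mean, mean(c(0.5, 1, 1)))
  expect_equal(p$sd, sqrt(mean((c(0.5, 1, 1) - 5/6)^2)))
  expect_true(p$q25 <= p$median && p$median <= p$q75)

  # single scan: degenerate distribution
  cs1 <- cohort_summary(scan_metrics(tp = 1, fp = 1, fn = 1))
  s1 <- cs1$stats[cs1$stats$metric == "recall", ]
  expect_equal(c(s1$mean, s1$median, s1$sd), c(0.5, 0.5, 0))
  expect_equal(s1$q25, s1$q75)

  # undefined scans are excluded and counted
  per2 <- rbind(scan_metrics(tp = 0, fp = 0, fn = 2, scan_id = "a"),
                scan_metrics(tp = 1, fp = 1, fn = 0, scan_id = "b"))
  cs2 <- cohort_summary(per2)
  p2 <- cs2$stats[cs2$stats$metric == "precision", ]
  expect_equal(p2$n_excluded, 1L)
  expect_equal(p2$mean, 0.5)
  # all-undefined metric yields the insufficient-data marker
  cs3 <- cohort_summary(scan_metrics(tp = 0, fp = 0, fn = 3))
  expect_true(is.na(cs3$stats[cs3$stats$metric == "precision", "mean"]))
})

test_that("pooled counts equal per-scan sums on randomized cohorts", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    per <- do.call(rbind, lapply(seq_len(n), function(i)
      scan_metrics(tp = sample(0:5, 1), fp = sample(0:5, 1),
                   fn = sample(0:5, 1), scan_id = as.character(i))))
    cs <- cohort_summary(per)
    expect_equal(cs$pooled$tp, sum(per$tp))
    expect_equal(cs$pooled$fp, sum(per$fp))
    expect_equal(cs$pooled$fn, sum(per$fn))
    # permutation invariance of the aggregation
    cs_perm <- cohort_summary(per[sample(n), ])
    expect_equal(cs_perm$stats, cs$stats)
    expect_equal(cs_perm$pooled[-1], cs$pooled[-1])
  }
})

test_that("summary delta reports percentage-point differences", {
  expect_equal(summary_delta(c(median_precision = 84.9),
                             c(median_precision = 66.7)),
               c(median_precision = 18.2))
  a <- cohort_summary(rbind(scan_metrics(tp = 2, fp = 0, fn = 0),
                            scan_metrics(tp = 1, fp = 1, fn = 1)))
  b <- cohort_summary(rbind(scan_metrics(tp = 1, fp = 1, fn = 1),
                            scan_metrics(tp = 1, fp = 3, fn = 1)))
  d <- summary_delta(a, b)
  expect_equal(d$stats$median[d$stats$metric == "precision"],
               0.75 - 0.375)
  expect_equal(d$pooled$tp, 1)
})

test_that("evaluate applies the size filter to predictions only", {
  ph <- generate_phantom(small_phantom_spec(13, n_lesions = 4))
  # prediction = GT plus one small spurious blob
  pred <- degrade_prediction(ph$gt, degradation_spec(
    n_inject = 1, inject_semiaxes = c(1.5, 2.2), seed = 4))
  blob_vox <- attr(pred, "injected")$voxels
  expect_lt(blob_vox, 250)
  ev0 <- evaluate(ph$gt, pred, size_threshold = 0)
  expect_equal(c(ev0$metrics$tp, ev0$metrics$fp, ev0$metrics$fn), c(4, 1, 0))
  ev250 <- evaluate(ph$gt, pred, size_threshold = 250)
  expect_equal(ev250$metrics$fp, 0)
  # the filter never creates FNs: GT components below threshold still count
  small_gt_sizes <- extract_components(ph$gt)$voxels
  ev_bigthr <- evaluate(ph$gt, ph$gt, size_threshold = max(small_gt_sizes))
  expect_equal(ev_bigthr$metrics$fn + ev_bigthr$metrics$tp, 4)
})

test_that("evaluate handles multi-class label maps via the lesion code", {
  ph <- generate_phantom(small_phantom_spec(17, n_lesions = 3))
  lm <- merge_with_body(ph$gt, ph$body)  # codes 0/1/2
  ev <- evaluate(ph$gt, lm, size_threshold = 0)
  expect_equal(c(ev$metrics$precision, ev$metrics$recall), c(1, 1))
  ev5 <- evaluate(lm, lm, lesion_code = 2L)
  expect_equal(ev5$metrics$tp, 3)
})

test_that("threshold sweep is monotone and anchored at the unfiltered counts", {
  ph <- generate_phantom(small_phantom_spec(29, n_lesions = 5))
  pred <- degrade_prediction(ph$gt, degradation_spec(
    n_drop = 1, n_inject = 3, inject_semiaxes = c(1.5, 4), jitter = 1,
    seed = 8))
  sizes <- extract_components(pred)$voxels
  thresholds <- c(0, sort(unique(sizes)), max(sizes) + 1)
  res <- t(vapply(thresholds, function(th) {
    m <- evaluate(ph$gt, pred, size_threshold = th)$metrics
    c(tp = m$tp, fp = m$fp, fn = m$fn)
  }, c(tp = 0, fp = 0, fn = 0)))
  expect_true(all(diff(res[, "tp"]) <= 0))
  expect_true(all(diff(res[, "fp"]) <= 0))
  expect_true(all(diff(res[, "fn"]) >= 0))
  expect_true(all(res[, "tp"] + res[, "fn"] == 5))  # conservation everywhere
  unfiltered <- match_lesions(ph$gt, array(as.logical(pred), dim = dim(pred)))
  expect_equal(unname(res[1, ]),
               c(unfiltered$tp, unfiltered$fp, unfiltered$fn))
})
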