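make_table <- function(gt_sizes, pred_sizes, pairs) {
  structure(list(pairs = pairs,
                 gt_sizes = gt_sizes, pred_sizes = pred_sizes,
                 n_voxels = sum(gt_sizes) + sum(pred_sizes)),
            class = "overlap_table")
}

test_that("cost matrix entries follow the indicator + tie-break form", {
  # single pair, IoU 0.8, N = 1: C = -1 - 0.8/2 = -1.4
  tab <- make_table(c(`1` = 100L), c(`1` = 100L),
                    data.frame(gt_id = 1L, pred_id = 1L,
                               intersection = 89L))  # IoU 89/111 ~ 0.8018
  i <- 89 / 111
  cm <- build_cost_matrix(tab, T = 0.75)
  expect_equal(cm[1, 1], -1 - i / 2)
  # sub-threshold: indicator off
  tab2 <- make_table(c(`1` = 100L), c(`1` = 100L),
                     data.frame(gt_id = 1L, pred_id = 1L,
                                intersection = 50L))  # IoU 1/3
  cm2 <- build_cost_matrix(tab2, T = 0.75)
  expect_equal(cm2[1, 1], -(1 / 3) / 2)
  # zero overlap costs exactly 0
  tab3 <- make_table(c(`1` = 10L, `2` = 10L), c(`1` = 10L),
                     data.frame(gt_id = 1L, pred_id = 1L,
                                intersection = 10L))
  cm3 <- build_cost_matrix(tab3, T = 0.75)
  expect_equal(cm3["1", "2"], 0)
  # all entries in [-1 - 1/(2N), 0]
  expect_true(all(cm3 <= 0 & cm3 >= -1 - 1 / (2 * attr(cm3, "N"))))
})

test_that("simple assignments resolve as expected at T = 0.75", {
  # 1 GT, 1 pred, IoU ~0.8 -> TP
  a <- array(0L, c(2, 5, 5))
  b <- a
  a[, 1:2, 1:5] <- 1L  # 20 voxels
  b[, 1:2, 1:4] <- 1L  # 16 voxels, all inside: IoU 16/20 = 0.8
  m <- hungarian_match(label_volume(a), label_volume(b))
  expect_identical(nrow(m$tp_pairs), 1L)
  expect_length(m$fp_pred_ids, 0)
  expect_length(m$fn_gt_ids, 0)

  # 1 GT, 2 preds with IoU 0.8 and lower: higher IoU wins, other is FP
  b2 <- array(0L, c(2, 5, 5))
  b2[, 1:2, 1:4] <- 1L  # IoU 0.8
  b2[, 1:2, 5] <- 2L    # IoU 4/20 = 0.2
  m2 <- hungarian_match(label_volume(a), label_volume(b2))
  expect_identical(m2$tp_pairs$pred_id, 1L)
  expect_identical(m2$fp_pred_ids, 2L)
})

test_that("assignment cost equals the exhaustive brute-force minimum", {
  for (seed in 1:40) {
    pair <- random_pair(seed)
    tab <- overlap_table(pair$gt, pair$pred)
    cm <- build_cost_matrix(tab, 0.75)
    m <- optimal_assignment(cm)
    achieved <- 0
    if (nrow(m$assignment)) {
      achieved <- sum(cm[cbind(as.character(m$assignment$pred_id),
                               as.character(m$assignment$gt_id))])
    }
    oracle <- brute_force_assignment_cost(
      matrix(as.numeric(cm), nrow(cm), ncol(cm)))
    expect_equal(achieved, oracle, tolerance = 1e-12)
  }
})

test_that("TP + FN = #GT and TP + FP = #pred, always", {
  for (seed in c(1, 9, 23, 31)) {
    pair <- random_pair(seed)
    m <- hungarian_match(pair$gt, pair$pred)
    expect_identical(nrow(m$tp_pairs) + length(m$fn_gt_ids), m$n_gt)
    expect_identical(nrow(m$tp_pairs) + length(m$fp_pred_ids), m$n_pred)
    # one-to-one: no id repeated
    expect_false(anyDuplicated(m$assignment$gt_id) > 0)
    expect_false(anyDuplicated(m$assignment$pred_id) > 0)
  }
})

test_that("the IoU tie-break term never flips a threshold decision", {
  # with distinct supra-threshold IoUs, dropping the -IoU/(2N) term must
  # leave the TP count unchanged
  for (seed in 1:15) {
    pair <- random_pair(seed)
    tab <- overlap_table(pair$gt, pair$pred)
    cm <- build_cost_matrix(tab, 0.5)
    iou_m <- attr(cm, "iou")
    supra <- iou_m[iou_m >= 0.5]
    if (anyDuplicated(supra)) next
    m_full <- optimal_assignment(cm)
    cm_ind <- cm
    cm_ind[] <- -(iou_m >= 0.5)  # indicator-only cost
    attr(cm_ind, "T") <- 0.5
    attr(cm_ind, "iou") <- iou_m
    m_ind <- optimal_assignment(cm_ind)
    expect_identical(nrow(m_full$tp_pairs), nrow(m_ind$tp_pairs))
  }
})

test_that("matching scores follow their definitions and 0/0 gives 0", {
  m <- structure(list(
    assignment = data.frame(gt_id = 1:2, pred_id = 1:2, iou = c(0.9, 0.8)),
    tp_pairs = data.frame(gt_id = 1:2, pred_id = 1:2, iou = c(0.9, 0.8)),
    fp_pred_ids = 3L, fn_gt_ids = 3L, T = 0.75, n_gt = 3L, n_pred = 3L),
    class = "match_result")
  sc <- matching_scores(m)
  expect_equal(sc$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(sc$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(sc$accuracy, 0.5, tolerance = 1e-12)

  # empty prediction: all scores 0
  gt <- tiny_pair()
  empty <- label_volume(array(0L, dim(gt$grid)), gt$spacing)
  m0 <- hungarian_match(gt, empty)
  sc0 <- matching_scores(m0)
  expect_equal(unlist(sc0[, c("precision", "recall", "accuracy")]),
               c(precision = 0, recall = 0, accuracy = 0))

  # perfect prediction: all 1
  mp <- hungarian_match(gt, gt)
  scp <- matching_scores(mp)
  expect_equal(unlist(scp[, c("precision", "recall", "accuracy")]),
               c(precision = 1, recall = 1, accuracy = 1))
})

test_that("accuracy never exceeds precision or recall when TP > 0", {
  for (seed in c(2, 8, 14)) {
    pair <- random_pair(seed)
    sc <- matching_scores(hungarian_match(pair$gt, pair$pred, T = 0.3))
    if (sc$TP > 0) {
      expect_lte(sc$accuracy, min(sc$precision, sc$recall) + 1e-12)
    }
  }
})

test_that("scores are invariant under relabeling and joint axis permutation", {
  pair <- random_pair(4)
  base <- matching_scores(hungarian_match(pair$gt, pair$pred, T = 0.5))
  # relabel both sides
  g2 <- relabel_consecutive(label_volume(pair$gt$grid * 7L,
                                         pair$gt$spacing))$volume
  p2 <- relabel_consecutive(label_volume(pair$pred$grid * 5L,
                                         pair$pred$spacing))$volume
  expect_equal(matching_scores(hungarian_match(g2, p2, T = 0.5)), base)
  # joint permutation of axes (z,y,x) -> (y,x,z) with spacing permuted
  perm <- c(2, 3, 1)
  gp <- label_volume(aperm(pair$gt$grid, perm), pair$gt$spacing[perm])
  pp <- label_volume(aperm(pair$pred$grid, perm), pair$pred$spacing[perm])
  expect_equal(matching_scores(hungarian_match(gp, pp, T = 0.5)), base)
})

test_that("per-group scores bin FN by GT group and FP by prediction group", {
  sc <- build_toy_scene()
  tab <- overlap_table(sc$gt, sc$pred)
  m <- hungarian_match(table = tab)
  gg <- size_grouping(sc$gt)
  pg <- size_grouping(sc$pred)
  s <- matching_scores(m, gt_grouping = gg, pred_grouping = pg, table = tab)
  med <- s[s$scope == "medium", ]
  expect_identical(med$TP, 2L)
  expect_identical(med$FN, 1L)
  expect_equal(med$recall, 2 / 3, tolerance = 1e-12)
  # group counts are consistent with the total row
  tot <- s[s$scope == "total", ]
  expect_identical(sum(s$TP[s$scope != "total"]), tot$TP)
  expect_identical(sum(s$FN[s$scope != "total"]), tot$FN)
  expect_identical(sum(s$FP[s$scope != "total"]), tot$FP)
})
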