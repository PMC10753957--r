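test_that("the default toy scene realizes its printed structure", {
  sc <- build_toy_scene()
  expect_length(instance_ids(sc$gt), 6)
  grp <- size_grouping(sc$gt)
  expect_identical(sort(table(grp$group), method = "radix"),
                   sort(table(c(rep("small", 2), rep("medium", 3),
                                "large")), method = "radix"))
  # the planned categories are exactly what the association module reports
  res <- categorize_associations(association_graph(
    overlap_table(sc$gt, sc$pred)))
  expect_identical(res$gt_category$category,
                   unname(sc$plan$gt_category))
  expect_length(res$background_preds, 5)
  # zero-FP variant: background percentage 0
  sc0 <- build_toy_scene(toy_scene_spec(n_fp = 0))
  res0 <- categorize_associations(association_graph(
    overlap_table(sc0$gt, sc0$pred)))
  expect_length(res0$background_preds, 0)
})

test_that("toy scene overlap structure matches the error plan", {
  sc <- build_toy_scene()
  pr <- iou_pairs(overlap_table(sc$gt, sc$pred))
  roles <- sc$plan$pred_role
  # exact matches reach the threshold; merger and split pieces stay below
  expect_true(all(pr$iou[pr$pred_id %in% which(roles == "exact")] >= 0.75))
  expect_true(all(pr$iou[pr$pred_id %in%
                           which(roles != "exact")] < 0.75))
  # split pieces overlap only the large instance, exclusively
  pieces <- which(roles == "split_piece")
  expect_identical(sort(unique(pr$gt_id[pr$pred_id %in% pieces])),
                   sc$plan$large_id)
  expect_identical(sum(pr$pred_id %in% pieces),
                   sc$plan$large_pieces)
  # the merged prediction overlaps exactly the planned pair
  merger <- which(roles == "merger")
  expect_identical(sort(pr$gt_id[pr$pred_id == merger]),
                   sort(sc$plan$merged_gt))
})

test_that("toy scene construction is seed-reproducible", {
  a <- build_toy_scene(seed = 4)
  b <- build_toy_scene(seed = 4)
  c <- build_toy_scene(seed = 5)
  expect_identical(a$pred$grid, b$pred$grid)
  expect_false(identical(a$pred$grid, c$pred$grid))
  expect_identical(a$gt$grid, c$gt$grid)  # GT geometry is deterministic
})

test_that("error plans validate their references", {
  expect_error(error_plan(split = list(2L)), "named")
  expect_error(error_plan(split = list(`1` = 1L)), ">= 2")
  expect_error(error_plan(merge = list(1L)), ">= 2")
  expect_error(error_plan(split = list(`1` = 2L), drop = 1L), "at most one")
  gt <- random_scene(3, seed = 2)
  expect_error(inject_errors(gt, error_plan(drop = 9L)), "unknown gt ids")
})

test_that("inject_errors realizes splits, merges, drops and FPs exactly", {
  gt <- random_scene(6, shape = c(24, 40, 40), size_range = c(3, 6),
                     seed = 17)
  plan <- error_plan(split = list(`2` = 3L), merge = list(c(4L, 5L)),
                     drop = 6L, n_fp = 2L, seed = 9)
  pred <- inject_errors(gt, plan)
  pr <- iou_pairs(overlap_table(gt, pred))
  # split: exactly 3 pred ids overlap gt 2, each exclusively
  p2 <- pr$pred_id[pr$gt_id == 2L]
  expect_length(p2, 3)
  expect_true(all(pr$gt_id[pr$pred_id %in% p2] == 2L))
  # merge: one pred id overlaps both gt 4 and gt 5
  p45 <- intersect(pr$pred_id[pr$gt_id == 4L], pr$pred_id[pr$gt_id == 5L])
  expect_length(p45, 1)
  # drop: gt 6 overlaps nothing
  expect_false(any(pr$gt_id == 6L))
  # FPs: 2 predictions overlap no gt
  all_pred <- instance_ids(pred)
  expect_length(setdiff(all_pred, pr$pred_id), 2)
  # reproducibility: same plan -> identical volumes; other fp seed differs
  expect_identical(inject_errors(gt, plan)$grid, pred$grid)
  plan2 <- error_plan(split = list(`2` = 3L), merge = list(c(4L, 5L)),
                      drop = 6L, n_fp = 2L, seed = 10)
  expect_false(identical(inject_errors(gt, plan2)$grid, pred$grid))
})

test_that("rendered probability maps are clean indicators with contour shells", {
  # noise 0, single cube: fg exactly 1 inside, 0 outside
  g <- array(0L, c(8, 8, 8))
  g[3:6, 3:6, 3:6] <- 1L
  v <- label_volume(g)
  maps <- render_bc_probabilities(v, noise_sd = 0)
  expect_equal(maps$fg$grid, array(as.numeric(g > 0), dim(g)))
  # the cube is entirely shell except its 2x2x2 core
  expect_equal(sum(maps$contour$grid), 64 - 8)
  # touching blobs get a contour ridge on the shared interface
  tp <- blob_scene(2, touching = TRUE)
  m2 <- render_bc_probabilities(tp)
  interface <- which(tp$grid > 0 & m2$contour$grid > 0)
  expect_gt(length(interface), 0)
  # noise is seeded and clipped
  mn1 <- render_bc_probabilities(v, noise_sd = 0.1, seed = 3)
  mn2 <- render_bc_probabilities(v, noise_sd = 0.1, seed = 3)
  mn3 <- render_bc_probabilities(v, noise_sd = 0.1, seed = 4)
  expect_identical(mn1$fg$grid, mn2$fg$grid)
  expect_false(identical(mn1$fg$grid, mn3$fg$grid))
  expect_true(min(mn1$fg$grid) >= 0 && max(mn1$fg$grid) <= 1)
})

test_that("random scenes are seeded and non-overlapping", {
  a <- random_scene(8, seed = 21)
  b <- random_scene(8, seed = 21)
  c <- random_scene(8, seed = 22)
  expect_identical(a$grid, b$grid)
  expect_false(identical(a$grid, c$grid))
  expect_length(instance_ids(a), 8)
  # instances never touch: each is its own 26-connected component
  idx <- build_index(a)
  for (id in idx$ids) {
    cr <- mitometrics:::crop_instance(a, idx, id)
    other <- a$grid[a$grid != 0L & a$grid != id]
    expect_identical(sum(cr$mask), unname(idx$sizes[as.character(id)]))
  }
})
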