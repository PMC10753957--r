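test_that("decoder params enforce threshold ordering", {
  expect_error(decoder_params(theta_seed = 0.5, theta_fg = 0.6),
               "theta_seed")
  h <- decoder_preset("mitoem-h")
  expect_equal(c(h$theta_seed, h$theta_contour, h$theta_fg),
               c(0.7, 0.6, 0.6))
  r <- decoder_preset("mitoem-r")
  expect_equal(c(r$theta_seed, r$theta_contour, r$theta_fg),
               c(0.85, 0.6, 0.8))
  expect_identical(h$min_voxels, 1024L)
})

test_that("seed extraction combines foreground AND low contour", {
  d <- c(4, 8, 8)
  zero <- prob_volume(array(0, d))
  one_blob <- array(0, d)
  one_blob[, 2:7, 2:3] <- 1
  one_blob[, 2:7, 6:7] <- 1
  fg <- prob_volume(one_blob)
  params <- decoder_params(min_voxels = 0)
  # no foreground -> no seeds
  expect_length(instance_ids(extract_seeds(zero, zero, params)), 0)
  # two blobs, no contour -> 2 seed labels
  expect_length(instance_ids(extract_seeds(fg, zero, params)), 2)
  # contour everywhere high -> 0 seeds
  high <- prob_volume(array(1, d))
  expect_length(instance_ids(extract_seeds(fg, high, params)), 0)
  # a high-contour ridge splits one blob into two seeds
  bar <- array(0, d)
  bar[, 2:7, 2:7] <- 1
  ridge <- array(0, d)
  ridge[, 2:7, 4:5] <- 1
  seeds <- extract_seeds(prob_volume(bar), prob_volume(ridge), params)
  expect_length(instance_ids(seeds), 2)
})

test_that("watershed floods the mask from seeds deterministically", {
  d <- c(3, 5, 12)
  fg <- array(0, d)
  fg[, 2:4, 2:11] <- 1
  fg[, 3, 6:7] <- 0.65  # shallow neck in the middle
  fg[, c(2, 4), 6:7] <- 0
  fgv <- prob_volume(fg)
  seeds <- array(0L, d)
  seeds[2, 3, 3] <- 1L
  seeds[2, 3, 10] <- 2L
  params <- decoder_params(theta_seed = 0.7, theta_fg = 0.6,
                           min_voxels = 0)
  lab <- watershed_decode(fgv, label_volume(seeds), params)
  # output confined to the mask, instances disjoint, each contains its seed
  expect_true(all(lab$grid[fg < 0.6] == 0L))
  expect_identical(lab$grid[2, 3, 3], 1L)
  expect_identical(lab$grid[2, 3, 10], 2L)
  expect_length(instance_ids(lab), 2)
  # the dumbbell splits at the neck: left lobe is 1, right lobe is 2
  expect_true(all(lab$grid[, 2:4, 2:5][fg[, 2:4, 2:5] >= 0.6] == 1L))
  expect_true(all(lab$grid[, 2:4, 8:11][fg[, 2:4, 8:11] >= 0.6] == 2L))
  # identical inputs give identical labels
  lab2 <- watershed_decode(fgv, label_volume(seeds), params)
  expect_identical(lab2$grid, lab$grid)
  # a seed outside the mask is an error
  bad <- array(0L, d)
  bad[1, 1, 1] <- 1L
  expect_error(watershed_decode(fgv, label_volume(bad), params),
               "outside")
  # no seeds -> empty labeling
  none <- watershed_decode(fgv, label_volume(array(0L, d)), params)
  expect_length(instance_ids(none), 0)
})

test_that("size filtering applies the strict fewer-than rule", {
  d <- c(12, 16, 16)
  g <- array(0L, d)
  g[1:4, 1:16, 1:16] <- 1L            # 1024 voxels: kept
  g[6:9, 1:16, 1:15] <- 2L            # 960 voxels: removed at 1024
  v <- label_volume(g)
  f <- filter_small_instances(v, 1024)
  expect_identical(instance_ids(f), 1L)
  # boundary: exactly 1023 is removed, 1024 kept
  g2 <- array(0L, d)
  g2[1:4, 1:16, 1:16] <- 1L
  g2[1, 1, 1] <- 0L                   # 1023 voxels
  expect_length(instance_ids(filter_small_instances(label_volume(g2),
                                                    1024)), 0)
  # min 0 is the identity
  expect_identical(filter_small_instances(v, 0)$grid, v$grid)
})

test_that("median filtering matches a brute-force window scan", {
  # constant volume unchanged
  const <- prob_volume(array(0.4, c(4, 5, 6)))
  expect_equal(median_filter_yz(const, 1)$grid, const$grid)
  # single impulse removed at radius 1
  imp <- array(0, c(5, 5, 3))
  imp[3, 3, 2] <- 1
  out <- median_filter_yz(prob_volume(imp), 1)
  expect_equal(max(out$grid), 0)
  # checkerboard and random volumes equal the sliding-window oracle
  set.seed(33)
  for (arr in list(
    array(as.numeric((slice.index(array(0, c(6, 7, 2)), 1) +
                        slice.index(array(0, c(6, 7, 2)), 2)) %% 2),
          c(6, 7, 2)),
    array(runif(6 * 7 * 2), c(6, 7, 2)))) {
    got <- median_filter_yz(prob_volume(arr), 1)$grid
    expect_equal(got, oracle_median_yz(arr, 1))
  }
})

test_that("decode recovers well-separated instances one-to-one", {
  gt <- blob_scene(3)
  maps <- render_bc_probabilities(gt)
  dec <- decode(maps$fg, maps$contour, decoder_preset("mitoem-h"))
  expect_length(instance_ids(dec), 3)
  res <- categorize_associations(association_graph(
    overlap_table(gt, dec)))
  expect_true(all(res$gt_category$category == "one_to_one"))
  # instance count never exceeds seed-component count
  seeds <- extract_seeds(maps$fg, maps$contour, decoder_preset("mitoem-h"))
  expect_lte(length(instance_ids(dec)), length(instance_ids(seeds)))
  # raising min_voxels never increases the instance count
  fewer <- decode(maps$fg, maps$contour,
                  decoder_preset("mitoem-h", min_voxels = 3000))
  expect_lte(length(instance_ids(fewer)), length(instance_ids(dec)))
})

test_that("a contour ridge separates touching blobs; zeroing it merges them", {
  gt <- blob_scene(2, touching = TRUE)
  maps <- render_bc_probabilities(gt)
  with_ridge <- decode(maps$fg, maps$contour, decoder_preset("mitoem-h"))
  expect_length(instance_ids(with_ridge), 2)
  zero <- prob_volume(array(0, dim(maps$contour$grid)),
                      maps$contour$spacing)
  merged <- decode(maps$fg, zero, decoder_preset("mitoem-h"))
  expect_length(instance_ids(merged), 1)
  res <- categorize_associations(association_graph(
    overlap_table(gt, merged)))
  expect_identical(res$gt_category$category,
                   rep("under_segmentation", 2))
})
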