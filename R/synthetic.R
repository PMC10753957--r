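#' Specification of the six-instance toy scene
#'
#' Describes the schematic validation scene: six ground-truth instances
#' (by default two small, three medium, one large by cable length) built
#' as axis-z tubes on an anisotropic grid, with a prediction that realizes
#' a fixed error plan: every instance except two is covered exactly
#' (IoU >= 0.75); one small and one medium instance are covered jointly by
#' a single merged prediction (IoU < 0.75 with each); the large instance
#' is covered by `large_pieces` disjoint predictions, each overlapping
#' only it with IoU < 0.75; and `n_fp` predictions overlap no ground
#' truth. Tube lengths (in voxels along z) are chosen so every instance
#' sits safely inside its cable-length group under the default 30 x 8 x 8
#' nm spacing.
#'
#' @param n_small,n_medium number of small / medium ground-truth tubes
#'   (each at least 1; the merger consumes one of each).
#' @param large_pieces number of disjoint pieces covering the large
#'   instance (>= 2).
#' @param n_fp number of background false-positive tubes.
#' @param thickness tube cross-section side in voxels (y and x).
#' @param spacing voxel size in nm (z, y, x).
#' @param len_small,len_small_merged,len_medium,len_medium_merged,len_large,len_fp
#'   tube lengths in voxels along z.
#' @return A `toy_scene_spec` list.
#' @export
toy_scene_spec <- function(n_small = 2L, n_medium = 3L, large_pieces = 3L,
                           n_fp = 5L, thickness = 3L,
                           spacing = c(30, 8, 8),
                           len_small = 20L, len_small_merged = 30L,
                           len_medium = 68L, len_medium_merged = 40L,
                           len_large = 150L, len_fp = 12L) {
  if (n_small < 1L || n_medium < 1L) {
    stop("need at least one small and one medium instance (the merged pair)",
         call. = FALSE)
  }
  if (large_pieces < 2L) stop("large_pieces must be >= 2", call. = FALSE)
  if (n_fp < 0L) stop("n_fp must be >= 0", call. = FALSE)
  structure(list(n_small = as.integer(n_small),
                 n_medium = as.integer(n_medium),
                 large_pieces = as.integer(large_pieces),
                 n_fp = as.integer(n_fp),
                 thickness = as.integer(thickness),
                 spacing = as.numeric(spacing),
                 len_small = as.integer(len_small),
                 len_small_merged = as.integer(len_small_merged),
                 len_medium = as.integer(len_medium),
                 len_medium_merged = as.integer(len_medium_merged),
                 len_large = as.integer(len_large),
                 len_fp = as.integer(len_fp)),
            class = "toy_scene_spec")
}

# paint an axis-z tube of square cross-section into `arr`
paint_tube <- function(arr, id, z0, len, yc, xc, half) {
  arr[z0:(z0 + len - 1L), (yc - half):(yc + half),
      (xc - half):(xc + half)] <- id
  arr
}

#' Build the six-instance toy scene
#'
#' Constructs ground truth and prediction per [toy_scene_spec()] and
#' verifies post hoc that the construction realizes the plan: cable-length
#' groups as intended, exact matches at IoU >= 0.75, merged and split
#' overlaps below 0.75, split pieces exclusive to the large instance, and
#' false positives overlapping nothing. The construction is deterministic
#' except for the z placement of the background false positives, which is
#' drawn under `seed`.
#'
#' @param spec a [toy_scene_spec()].
#' @param seed RNG seed for false-positive placement.
#' @return List with `gt` and `pred` ([label_volume()]s) and `plan`
#'   (expected association category per ground-truth id, the pred-side
#'   roles, and the group of every ground-truth instance).
#' @export
build_toy_scene <- function(spec = toy_scene_spec(), seed = 1L) {
  half <- (spec$thickness - 1L) %/% 2L
  zpad <- 6L
  col_w <- 4L * spec$thickness
  # row 1 (y = yc1): small/medium exact tubes + the merged pair's column;
  # row 2 (y = yc2): the large tube and the false positives
  yc1 <- 2L + half + 1L
  yc2 <- yc1 + 4L * spec$thickness
  n_row1 <- (spec$n_small - 1L) + (spec$n_medium - 1L) + 1L
  n_row2 <- 1L + spec$n_fp
  xs1 <- 2L + half + 1L + col_w * (seq_len(n_row1) - 1L)
  xs2 <- 2L + half + 1L + col_w * (seq_len(n_row2) - 1L)
  nz <- zpad + max(spec$len_large,
                   spec$len_small_merged + 8L + spec$len_medium_merged,
                   spec$len_medium) + zpad
  ny <- yc2 + half + 2L
  nx <- max(c(xs1, xs2)) + half + 2L
  gt <- array(0L, c(nz, ny, nx))
  pred <- array(0L, c(nz, ny, nx))

  gt_id <- 0L
  gt_group <- character()
  plan_cat <- character()
  col <- 0L
  # small exact matches
  for (k in seq_len(spec$n_small - 1L)) {
    gt_id <- gt_id + 1L
    col <- col + 1L
    gt <- paint_tube(gt, gt_id, zpad, spec$len_small, yc1, xs1[col], half)
    gt_group[gt_id] <- "small"
    plan_cat[gt_id] <- "one_to_one"
  }
  # merged pair: one small and one medium stacked in the same column
  merged_col <- col + 1L
  gt_id <- gt_id + 1L
  small_merged_id <- gt_id
  gt <- paint_tube(gt, gt_id, zpad, spec$len_small_merged, yc1,
                   xs1[merged_col], half)
  gt_group[gt_id] <- "small"
  plan_cat[gt_id] <- "under_segmentation"
  gap <- 8L
  gt_id <- gt_id + 1L
  medium_merged_id <- gt_id
  z_med <- zpad + spec$len_small_merged + gap
  gt <- paint_tube(gt, gt_id, z_med, spec$len_medium_merged, yc1,
                   xs1[merged_col], half)
  gt_group[gt_id] <- "medium"
  plan_cat[gt_id] <- "under_segmentation"
  col <- merged_col
  # medium exact matches
  for (k in seq_len(spec$n_medium - 1L)) {
    gt_id <- gt_id + 1L
    col <- col + 1L
    gt <- paint_tube(gt, gt_id, zpad, spec$len_medium, yc1, xs1[col], half)
    gt_group[gt_id] <- "medium"
    plan_cat[gt_id] <- "one_to_one"
  }
  # large instance
  gt_id <- gt_id + 1L
  large_id <- gt_id
  gt <- paint_tube(gt, gt_id, zpad, spec$len_large, yc2, xs2[1], half)
  gt_group[gt_id] <- "large"
  plan_cat[gt_id] <- "over_segmentation"

  # prediction: exact copies for the one-to-one instances
  pred_id <- 0L
  pred_role <- character()
  for (g in which(plan_cat == "one_to_one")) {
    pred_id <- pred_id + 1L
    pred[gt == g] <- pred_id
    pred_role[pred_id] <- "exact"
  }
  # merged prediction: union of the pair plus a 1-voxel connector line
  pred_id <- pred_id + 1L
  pred[gt == small_merged_id | gt == medium_merged_id] <- pred_id
  pred[(zpad + spec$len_small_merged):(z_med - 1L), yc1,
       xs1[merged_col]] <- pred_id
  pred_role[pred_id] <- "merger"
  # large split into contiguous z chunks
  bounds <- round(seq(zpad, zpad + spec$len_large,
                      length.out = spec$large_pieces + 1L))
  for (k in seq_len(spec$large_pieces)) {
    pred_id <- pred_id + 1L
    sel_z <- bounds[k]:(bounds[k + 1L] - 1L)
    sub <- gt[sel_z, , , drop = FALSE]
    psub <- pred[sel_z, , , drop = FALSE]
    psub[sub == large_id] <- pred_id
    pred[sel_z, , ] <- psub
    pred_role[pred_id] <- "split_piece"
  }
  # background false positives: random z placement on free columns
  if (spec$n_fp > 0L) {
    z_starts <- with_seed(seed, {
      sample.int(nz - spec$len_fp - 2L * zpad, spec$n_fp,
                 replace = TRUE) + zpad
    })
    for (k in seq_len(spec$n_fp)) {
      pred_id <- pred_id + 1L
      pred <- paint_tube(pred, pred_id, z_starts[k], spec$len_fp, yc2,
                         xs2[1L + k], half)
      pred_role[pred_id] <- "background"
    }
  }

  gt_vol <- label_volume(gt, spec$spacing)
  pred_vol <- label_volume(pred, spec$spacing)
  verify_toy_scene(gt_vol, pred_vol, plan_cat, gt_group, pred_role)
  list(gt = gt_vol, pred = pred_vol,
       plan = list(gt_category = plan_cat, gt_group = gt_group,
                   pred_role = pred_role,
                   large_id = large_id, large_pieces = spec$large_pieces,
                   merged_gt = c(small_merged_id, medium_merged_id)))
}

# post-hoc assertions: the construction must realize the printed outcome
# structure (group membership and IoU threshold relations)
verify_toy_scene <- function(gt, pred, plan_cat, gt_group, pred_role) {
  grouping <- size_grouping(gt)
  got <- grouping_lookup(grouping)[as.character(seq_along(gt_group))]
  if (!identical(unname(got), unname(gt_group))) {
    stop("toy scene construction failed: cable-length groups are ",
         paste(got, collapse = ","), " but the plan requires ",
         paste(gt_group, collapse = ","), call. = FALSE)
  }
  tab <- overlap_table(gt, pred)
  pr <- iou_pairs(tab)
  for (p in which(pred_role == "exact")) {
    if (max(pr$iou[pr$pred_id == p], 0) < 0.75) {
      stop("exact-match prediction ", p, " has IoU < 0.75", call. = FALSE)
    }
  }
  bad <- pr$iou[pr$pred_id %in% which(pred_role %in%
                                        c("merger", "split_piece"))]
  if (length(bad) && max(bad) >= 0.75) {
    stop("merged/split prediction reaches IoU >= 0.75", call. = FALSE)
  }
  if (any(pr$pred_id %in% which(pred_role == "background"))) {
    stop("background false positive overlaps ground truth", call. = FALSE)
  }
}

#' Random non-overlapping box scene
#'
#' Places `n_instances` axis-aligned boxes of random sizes on a background
#' grid by seeded rejection sampling; boxes never overlap (a 1-voxel
#' separation is enforced so instances also never touch).
#'
#' @param n_instances number of instances.
#' @param shape grid dim (nz, ny, nx).
#' @param size_range per-axis box side range in voxels (min, max).
#' @param spacing voxel size in nm (z, y, x).
#' @param seed RNG seed; identical seeds give identical volumes.
#' @param max_tries rejection-sampling budget per instance.
#' @return A [label_volume()] with ids 1..n_instances.
#' @export
random_scene <- function(n_instances, shape = c(24L, 48L, 48L),
                         size_range = c(3L, 8L), spacing = c(30, 8, 8),
                         seed = 1L, max_tries = 200L) {
  arr <- array(0L, shape)
  occupied <- array(FALSE, shape)  # dilated occupancy: keeps 1-voxel gaps
  with_seed(seed, {
    for (id in seq_len(n_instances)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        sz <- pmin(sample(size_range[1]:size_range[2], 3L, replace = TRUE),
                   shape)
        lo <- vapply(1:3, function(a) sample.int(shape[a] - sz[a] + 1L, 1L),
                     integer(1))
        zi <- lo[1]:(lo[1] + sz[1] - 1L)
        yi <- lo[2]:(lo[2] + sz[2] - 1L)
        xi <- lo[3]:(lo[3] + sz[3] - 1L)
        if (!any(occupied[zi, yi, xi])) {
          arr[zi, yi, xi] <- id
          zd <- max(lo[1] - 1L, 1L):min(lo[1] + sz[1], shape[1])
          yd <- max(lo[2] - 1L, 1L):min(lo[2] + sz[2], shape[2])
          xd <- max(lo[3] - 1L, 1L):min(lo[3] + sz[3], shape[3])
          occupied[zd, yd, xd] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place instance ", id, " after ", max_tries,
             " tries; use a larger grid or fewer instances", call. = FALSE)
      }
    }
  })
  label_volume(arr, spacing)
}

#' Seeded error plan for a ground-truth scene
#'
#' Describes how to corrupt a ground truth into a prediction:
#' `split` maps gt ids to piece counts, `merge` lists sets of gt ids to
#' fuse into one prediction, `drop` lists gt ids to omit (missing), `n_fp`
#' background false positives of size `fp_size` are added, and `jitter`
#' erodes each exact-copied instance by up to that many z slabs per end.
#'
#' @param split named list or vector, gt id -> number of pieces (>= 2).
#' @param merge list of integer vectors, each a set of >= 2 gt ids.
#' @param drop integer vector of gt ids to leave unpredicted.
#' @param n_fp number of background false positives.
#' @param fp_size false-positive box dim (z, y, x) in voxels.
#' @param jitter non-negative integer erosion amplitude for exact copies.
#' @param seed RNG seed for false-positive placement.
#' @return An `error_plan` list.
#' @export
error_plan <- function(split = list(), merge = list(), drop = integer(),
                       n_fp = 0L, fp_size = c(3L, 4L, 4L), jitter = 0L,
                       seed = 1L) {
  split <- as.list(split)
  if (length(split) && (is.null(names(split)) || any(names(split) == ""))) {
    stop("`split` must be named by gt id", call. = FALSE)
  }
  if (any(unlist(split) < 2L)) stop("split piece counts must be >= 2",
                                    call. = FALSE)
  if (any(vapply(merge, length, integer(1)) < 2L)) {
    stop("merge sets need >= 2 gt ids", call. = FALSE)
  }
  touched <- c(as.integer(names(split)), unlist(merge), as.integer(drop))
  if (anyDuplicated(touched)) {
    stop("a gt id may appear in at most one of split/merge/drop",
         call. = FALSE)
  }
  structure(list(split = split, merge = merge, drop = as.integer(drop),
                 n_fp = as.integer(n_fp), fp_size = as.integer(fp_size),
                 jitter = as.integer(jitter), seed = as.integer(seed)),
            class = "error_plan")
}

#' Corrupt a ground truth according to an error plan
#'
#' Splits partition an instance's voxels into the requested number of
#' pieces by cuts along its longest bounding-box axis; merges relabel the
#' listed instances to a single prediction id; dropped instances are
#' omitted; false positives are non-overlapping boxes placed on background
#' by seeded rejection sampling. Every remaining instance is copied
#' exactly (optionally eroded by `jitter` z slabs per end, staying inside
#' its ground truth). Deterministic under the plan's seed.
#'
#' @param gt a [label_volume()].
#' @param plan an [error_plan()].
#' @return A [label_volume()] prediction with an attribute `expected`:
#'   list with the expected association category per gt id and the number
#'   of background predictions.
#' @export
inject_errors <- function(gt, plan) {
  stopifnot(inherits(gt, "label_volume"), inherits(plan, "error_plan"))
  ids <- instance_ids(gt)
  touched <- c(as.integer(names(plan$split)), unlist(plan$merge), plan$drop)
  if (!all(touched %in% ids)) {
    stop("plan references unknown gt ids: ",
         paste(setdiff(touched, ids), collapse = ", "), call. = FALSE)
  }
  d <- dim(gt$grid)
  pred <- array(0L, d)
  expected <- setNames(rep("one_to_one", length(ids)), ids)
  next_id <- 0L
  v <- as.vector(gt$grid)
  # splits
  for (g in names(plan$split)) {
    k <- plan$split[[g]]
    vox <- which(v == as.integer(g))
    if (length(vox) < k) {
      stop("instance ", g, " has fewer voxels than requested pieces",
           call. = FALSE)
    }
    z <- (vox - 1L) %% d[1]
    y <- ((vox - 1L) %/% d[1]) %% d[2]
    x <- (vox - 1L) %/% (d[1] * d[2])
    ext <- c(diff(range(z)), diff(range(y)), diff(range(x)))
    axis <- which.max(ext)
    coord <- list(z, y, x)[[axis]]
    ord <- order(coord, vox)
    cuts <- ceiling(seq_len(k - 1L) * length(vox) / k)
    piece <- findInterval(seq_along(vox), c(cuts + 0.5)) + 1L
    for (pc in seq_len(k)) {
      next_id <- next_id + 1L
      pred[vox[ord][piece == pc]] <- next_id
    }
    expected[g] <- "over_segmentation"
  }
  # merges
  for (set in plan$merge) {
    next_id <- next_id + 1L
    pred[v %in% set] <- next_id
    expected[as.character(set)] <- "under_segmentation"
  }
  # drops
  expected[as.character(plan$drop)] <- "missing"
  # exact copies (optionally jittered)
  rest <- setdiff(ids, touched)
  for (g in rest) {
    next_id <- next_id + 1L
    vox <- which(v == g)
    if (plan$jitter > 0L) {
      z <- (vox - 1L) %% d[1]
      zr <- range(z)
      keep <- z >= zr[1] + plan$jitter & z <= zr[2] - plan$jitter
      if (any(keep)) vox <- vox[keep]
    }
    pred[vox] <- next_id
  }
  # background false positives
  if (plan$n_fp > 0L) {
    fs <- plan$fp_size
    with_seed(plan$seed, {
      placed <- 0L
      tries <- 0L
      while (placed < plan$n_fp && tries < 1000L) {
        tries <- tries + 1L
        lo <- vapply(1:3, function(a) {
          sample.int(max(d[a] - fs[a] + 1L, 1L), 1L)
        }, integer(1))
        zi <- lo[1]:min(lo[1] + fs[1] - 1L, d[1])
        yi <- lo[2]:min(lo[2] + fs[2] - 1L, d[2])
        xi <- lo[3]:min(lo[3] + fs[3] - 1L, d[3])
        if (!any(gt$grid[zi, yi, xi] != 0L) &&
            !any(pred[zi, yi, xi] != 0L)) {
          next_id <- next_id + 1L
          pred[zi, yi, xi] <- next_id
          placed <- placed + 1L
        }
      }
      if (placed < plan$n_fp) {
        stop("could not place all false positives on background",
             call. = FALSE)
      }
    })
  }
  out <- label_volume(pred, gt$spacing)
  attr(out, "expected") <- list(gt_category = expected,
                                n_background = plan$n_fp)
  out
}

# boundary voxels: any 26-neighbor with a different label (background
# counts, and so does the outside of the volume)
boundary_mask <- function(grid) {
  d <- dim(grid)
  bnd <- array(FALSE, d)
  fg <- grid > 0L
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- array(0L, d)
    src_z <- max(1, 1 - dz):min(d[1], d[1] - dz)
    src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
    src_x <- max(1, 1 - dx):min(d[3], d[3] - dx)
    shifted[src_z, src_y, src_x] <-
      grid[src_z + dz, src_y + dy, src_x + dx]
    bnd <- bnd | (fg & shifted != grid)
  }
  bnd
}

#' Render foreground and contour probability maps from a label volume
#'
#' Emulates the dual output of a BC-style network: the foreground map is
#' the instance indicator (1 inside, 0 outside) and the contour map is 1
#' on the 1-voxel boundary shell of every instance — including faces where
#' two instances touch — and 0 elsewhere. Optional additive Gaussian noise
#' (seeded) is clipped back to \[0, 1\].
#'
#' @param gt a [label_volume()].
#' @param noise_sd standard deviation of the additive noise (0 for clean
#'   maps).
#' @param seed RNG seed for the noise.
#' @return List with `fg` and `contour` ([prob_volume()]s).
#' @export
render_bc_probabilities <- function(gt, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(gt, "label_volume"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  fg <- array(as.numeric(gt$grid > 0L), dim(gt$grid))
  ct <- array(as.numeric(boundary_mask(gt$grid)), dim(gt$grid))
  if (noise_sd > 0) {
    with_seed(seed, {
      fg <- fg + rnorm(length(fg), 0, noise_sd)
      ct <- ct + rnorm(length(ct), 0, noise_sd)
    })
    fg <- pmin(pmax(fg, 0), 1)
    ct <- pmin(pmax(ct, 0), 1)
    dim(fg) <- dim(ct) <- dim(gt$grid)
  }
  list(fg = prob_volume(fg, gt$spacing),
       contour = prob_volume(ct, gt$spacing))
}

#' Grid of well-separated ellipsoidal blobs
#'
#' Arranges `k` ellipsoids (default radii 5 x 9 x 9 voxels, about 1700
#' voxels each) on a regular (y, x) grid with generous separation;
#' useful for end-to-end decoder recovery tests. With `touching = TRUE`,
#' `k` must be 2 and the pair abuts along y so the shared interface gets a
#' contour ridge when rendered.
#'
#' @param k number of blobs.
#' @param radii ellipsoid semi-axes in voxels (z, y, x).
#' @param spacing voxel size in nm (z, y, x).
#' @param touching place two abutting blobs instead of a separated grid.
#' @return A [label_volume()].
#' @export
blob_scene <- function(k = 10L, radii = c(5L, 9L, 9L),
                       spacing = c(30, 8, 8), touching = FALSE) {
  r <- as.integer(radii)
  if (touching) {
    if (k != 2L) stop("touching scenes have exactly 2 blobs", call. = FALSE)
    nz <- 2L * r[1] + 9L
    ny <- 4L * r[2] + 8L
    nx <- 2L * r[3] + 9L
    centers <- cbind(z = rep(nz %/% 2L, 2L),
                     y = c(3L + r[2], 3L + 3L * r[2] + 1L),
                     x = rep(nx %/% 2L, 2L))
  } else {
    ncol_b <- min(k, 5L)
    nrow_b <- ceiling(k / ncol_b)
    cell_y <- 2L * r[2] + 7L
    cell_x <- 2L * r[3] + 7L
    nz <- 2L * r[1] + 9L
    ny <- nrow_b * cell_y + 4L
    nx <- ncol_b * cell_x + 4L
    centers <- t(vapply(seq_len(k), function(i) {
      row <- (i - 1L) %/% ncol_b
      cl <- (i - 1L) %% ncol_b
      as.integer(c(z = nz %/% 2L, y = 2L + row * cell_y + cell_y %/% 2L,
                   x = 2L + cl * cell_x + cell_x %/% 2L))
    }, integer(3)))
  }
  arr <- array(0L, c(nz, ny, nx))
  zc <- slice.index(arr, 1) - 1L
  yc <- slice.index(arr, 2) - 1L
  xc <- slice.index(arr, 3) - 1L
  for (i in seq_len(k)) {
    inside <- ((zc - centers[i, 1]) / r[1])^2 +
      ((yc - centers[i, 2]) / r[2])^2 +
      ((xc - centers[i, 3]) / r[3])^2 <= 1
    arr[inside] <- i
  }
  label_volume(arr, spacing)
}
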