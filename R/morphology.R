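#' Skeletonize one instance mask
#'
#' 3D topological thinning of a binary mask to a curve skeleton (simple
#' border points are peeled while endpoints are kept), followed by graph
#' construction over the 26-connected skeleton voxels. Edge lengths are the
#' physical Euclidean distances between voxel centers under the anisotropic
#' spacing; a minimum spanning tree per connected component gives the
#' cycle-free subset used for length accounting, so thick junction
#' clusters are never double-counted.
#'
#' @param mask 3D logical (or 0/1) array; must contain at least one voxel.
#' @param spacing physical voxel size in nm (z, y, x).
#' @return A `skeleton_graph`: list with `nodes` (n x 3 matrix of 0-based
#'   voxel coordinates, columns z, y, x), `edges` and `tree` (data.frames
#'   `from`, `to`, `length_nm` indexing rows of `nodes`; `tree` is the
#'   spanning subset), and `n_components`.
#' @export
skeletonize_instance <- function(mask, spacing = c(30, 8, 8)) {
  if (length(dim(mask)) != 3L) stop("`mask` must be 3D", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  d <- dim(mask)
  skel <- skeletonize_3d(as.logical(mask), as.integer(d))
  idx <- which(skel)
  z <- (idx - 1L) %% d[1]
  y <- ((idx - 1L) %/% d[1]) %% d[2]
  x <- (idx - 1L) %/% (d[1] * d[2])
  nodes <- cbind(z = z, y = y, x = x)
  # 26-neighbor edges: enumerate 13 forward offsets only, so each pair once
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
                 (offs$dx == 0 & offs$dy == 0 & offs$dz > 0), , drop = FALSE]
  key <- idx  # linear index of each node
  node_of <- seq_along(idx)
  from <- integer(); to <- integer(); len <- numeric()
  for (k in seq_len(nrow(offs))) {
    zz <- z + offs$dz[k]; yy <- y + offs$dy[k]; xx <- x + offs$dx[k]
    ok <- zz >= 0 & zz < d[1] & yy >= 0 & yy < d[2] & xx >= 0 & xx < d[3]
    j <- 1L + zz[ok] + d[1] * (yy[ok] + d[2] * xx[ok])
    hit <- match(j, key)
    sel <- !is.na(hit)
    if (any(sel)) {
      from <- c(from, node_of[ok][sel])
      to <- c(to, hit[sel])
      step <- sqrt(sum((c(offs$dz[k], offs$dy[k], offs$dx[k]) * spacing)^2))
      len <- c(len, rep(step, sum(sel)))
    }
  }
  edges <- data.frame(from = from, to = to, length_nm = len)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = seq_along(idx)))
    igraph::E(g)$weight <- edges$length_nm
    mst <- igraph::mst(g, weights = igraph::E(g)$weight)
    el <- igraph::as_data_frame(mst, what = "edges")
    tree <- data.frame(from = as.integer(el$from), to = as.integer(el$to),
                       length_nm = el$weight)
    n_comp <- igraph::components(g)$no
  } else {
    tree <- edges
    n_comp <- nrow(nodes)
  }
  structure(list(nodes = nodes, edges = edges, tree = tree,
                 n_components = n_comp, spacing = as.numeric(spacing)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d edges (%d in tree), %d component%s\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$tree), x$n_components,
              if (x$n_components == 1) "" else "s"))
  invisible(x)
}

#' Cable length of a skeleton
#'
#' Sum of the spanning-tree edge lengths, converted from nm to um. A
#' single-voxel skeleton has length 0.
#'
#' @param skel a [skeletonize_instance()] result.
#' @return Length in um.
#' @export
cable_length <- function(skel) {
  stopifnot(inherits(skel, "skeleton_graph"))
  sum(skel$tree$length_nm) / 1000
}

#' Cable length of every instance in a label volume
#'
#' Each instance is cropped to its bounding box (1-voxel pad),
#' skeletonized, and measured with [cable_length()].
#'
#' @param vol a [label_volume()].
#' @param index optional precomputed [build_index()] result.
#' @return Named numeric vector, um per instance id.
#' @export
cable_lengths <- function(vol, index = build_index(vol)) {
  stopifnot(inherits(vol, "label_volume"))
  vapply(as.character(index$ids), function(id) {
    cr <- crop_instance(vol, index, as.integer(id))
    cable_length(skeletonize_instance(cr$mask, vol$spacing))
  }, numeric(1))
}

#' Group instances as small / medium / large by cable length
#'
#' Boundary convention: small when length <= 1 um, large when length >=
#' 4 um, medium strictly in between (thresholds configurable).
#'
#' @param lengths named numeric vector of cable lengths in um (names are
#'   instance ids).
#' @param thresholds numeric length-2 `(t_small, t_large)` in um.
#' @return A `size_grouping`: data.frame with `id`, `value`, `group`;
#'   attributes `mode = "length"` and `thresholds`.
#' @export
group_by_length <- function(lengths, thresholds = c(1, 4)) {
  if (any(lengths < 0)) stop("negative cable length", call. = FALSE)
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2]) {
    stop("`thresholds` must be two increasing values", call. = FALSE)
  }
  grp <- ifelse(lengths <= thresholds[1], "small",
                ifelse(lengths >= thresholds[2], "large", "medium"))
  structure(data.frame(id = as.integer(names(lengths)),
                       value = unname(lengths), group = unname(grp)),
            mode = "length", thresholds = thresholds,
            class = c("size_grouping", "data.frame"))
}

#' Group instances by voxel volume (legacy mode)
#'
#' Same boundary semantics as [group_by_length()] applied to voxel counts.
#' The voxel cutoffs are dataset-specific and must be supplied explicitly.
#'
#' @param sizes named integer vector of voxel counts per instance id.
#' @param thresholds numeric length-2 `(t_small, t_large)` in voxels;
#'   required.
#' @return A `size_grouping` with `mode = "volume"`.
#' @export
group_by_volume <- function(sizes, thresholds) {
  if (missing(thresholds) || is.null(thresholds)) {
    stop("volume grouping has no default thresholds; supply them",
         call. = FALSE)
  }
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2]) {
    stop("`thresholds` must be two increasing values", call. = FALSE)
  }
  grp <- ifelse(sizes <= thresholds[1], "small",
                ifelse(sizes >= thresholds[2], "large", "medium"))
  structure(data.frame(id = as.integer(names(sizes)),
                       value = as.numeric(unname(sizes)),
                       group = unname(grp)),
            mode = "volume", thresholds = thresholds,
            class = c("size_grouping", "data.frame"))
}

#' Size grouping of a label volume
#'
#' Convenience wrapper: measures cable lengths (or voxel volumes) and
#' applies the grouping rule.
#'
#' @param vol a [label_volume()].
#' @param mode `"length"` (cable length, um) or `"volume"` (voxels).
#' @param thresholds grouping thresholds; default `c(1, 4)` um for length
#'   mode, required for volume mode.
#' @param index optional precomputed [build_index()].
#' @return A `size_grouping`.
#' @export
size_grouping <- function(vol, mode = c("length", "volume"),
                          thresholds = NULL, index = build_index(vol)) {
  mode <- match.arg(mode)
  if (mode == "length") {
    if (is.null(thresholds)) thresholds <- c(1, 4)
    group_by_length(cable_lengths(vol, index), thresholds)
  } else {
    group_by_volume(index$sizes, thresholds)
  }
}

grouping_lookup <- function(grouping) {
  stopifnot(inherits(grouping, "size_grouping"))
  setNames(grouping$group, grouping$id)
}

#' Split and merger association pair sets
#'
#' Routes the non-one-to-one, non-missing association pairs into a split
#' set S and a merger set M. Over-segmentation pairs go to S and
#' under-segmentation pairs to M. A many-to-many pair (p, g) goes to S
#' when the ground-truth fan-out dominates (|A(g)| > |A'(p)|), to M when
#' the prediction-side merge dominates (|A'(p)| > |A(g)|), with ties to S.
#' The literal printed inequality (which attaches |A'(p)| >= |A(g)| to
#' splits and so excludes every pure over-segmentation pair) is available
#' via `as_printed = TRUE` for comparison.
#'
#' @param graph an [association_graph()].
#' @param categories the matching [categorize_associations()] result.
#' @param as_printed use the literal inequality orientation instead of the
#'   fan-out semantics.
#' @return A `split_merge_record`: list with `S` and `M` (data.frames
#'   `pred_id`, `gt_id`), `splits_per_gt` (named: |A(g)| for every g in an
#'   S pair), `merges_per_pred` (named: |A'(p)| for every p in an M pair).
#' @export
split_merge_sets <- function(graph, categories, as_printed = FALSE) {
  stopifnot(inherits(graph, "association_graph"),
            inherits(categories, "association_result"))
  cat_of <- setNames(categories$gt_category$category,
                     categories$gt_category$gt_id)
  pairs <- graph$pairs
  deg_g <- vapply(graph$A_of_g, length, integer(1))
  deg_p <- vapply(graph$A_of_p, length, integer(1))
  pc <- cat_of[as.character(pairs$gt_id)]
  ag <- deg_g[as.character(pairs$gt_id)]
  ap <- deg_p[as.character(pairs$pred_id)]
  if (as_printed) {
    in_S <- (pc %in% c("over_segmentation", "many_to_many")) & ap >= ag
    in_M <- (pc %in% c("under_segmentation", "many_to_many")) & ap < ag
  } else {
    in_S <- pc == "over_segmentation" | (pc == "many_to_many" & ag >= ap)
    in_M <- pc == "under_segmentation" | (pc == "many_to_many" & ap > ag)
  }
  S <- pairs[in_S, c("pred_id", "gt_id"), drop = FALSE]
  M <- pairs[in_M, c("pred_id", "gt_id"), drop = FALSE]
  rownames(S) <- rownames(M) <- NULL
  sg <- sort(unique(S$gt_id))
  mp <- sort(unique(M$pred_id))
  structure(list(S = S, M = M,
                 splits_per_gt = setNames(deg_g[as.character(sg)],
                                          as.character(sg)),
                 merges_per_pred = setNames(deg_p[as.character(mp)],
                                            as.character(mp)),
                 as_printed = as_printed),
            class = "split_merge_record")
}

#' @export
print.split_merge_record <- function(x, ...) {
  cat(sprintf("<split_merge_record> %d split pairs over %d GT, %d merger pairs over %d predictions\n",
              nrow(x$S), length(x$splits_per_gt),
              nrow(x$M), length(x$merges_per_pred)))
  invisible(x)
}

#' Split/merger counts binned by ground-truth cable length
#'
#' The ground-truth cable-length range is divided into `nbins` equal-width
#' bins; within each bin the mean and standard deviation of the
#' per-instance split count (|A(g)| for split instances, 0 otherwise) and
#' merger count (|A'(p)| of the merging prediction, 0 otherwise) are
#' reported alongside the bin occupancy.
#'
#' @param record a [split_merge_sets()] result.
#' @param lengths named numeric vector of ground-truth cable lengths (um)
#'   covering every ground-truth instance.
#' @param nbins number of equal-width bins (default 15).
#' @return data.frame with `bin`, `bin_lo`, `bin_hi`, `n_instances`,
#'   `mean_splits`, `sd_splits`, `mean_merges`, `sd_merges`.
#' @export
split_merge_histogram <- function(record, lengths, nbins = 15L) {
  stopifnot(inherits(record, "split_merge_record"))
  ids <- names(lengths)
  need <- unique(c(record$S$gt_id, record$M$gt_id))
  if (!all(as.character(need) %in% ids)) {
    stop("`lengths` must cover every ground-truth instance in the record",
         call. = FALSE)
  }
  splits <- setNames(numeric(length(ids)), ids)
  splits[names(record$splits_per_gt)] <- record$splits_per_gt
  merges <- setNames(numeric(length(ids)), ids)
  if (nrow(record$M)) {
    deg <- record$merges_per_pred[as.character(record$M$pred_id)]
    agg <- tapply(deg, record$M$gt_id, max)
    merges[names(agg)] <- agg
  }
  rng <- range(lengths)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  bin <- findInterval(lengths, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- do.call(rbind, lapply(seq_len(nbins), function(b) {
    sel <- bin == b
    data.frame(bin = b, bin_lo = breaks[b], bin_hi = breaks[b + 1],
               n_instances = sum(sel),
               mean_splits = if (any(sel)) mean(splits[sel]) else NA_real_,
               sd_splits = if (sum(sel) > 1) sd(splits[sel]) else NA_real_,
               mean_merges = if (any(sel)) mean(merges[sel]) else NA_real_,
               sd_merges = if (sum(sel) > 1) sd(merges[sel]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
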