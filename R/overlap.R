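#' Sparse ground-truth/prediction overlap table
#'
#' Builds the sparse contingency table between ground-truth and predicted
#' instances in one linear pass over paired voxels: every co-occurring
#' (gt_id, pred_id) label pair with its joint voxel count, plus the
#' per-instance sizes. Background (id 0) never appears. This table is the
#' single source for IoU, matching, AP and association analysis.
#'
#' @param gt,pred [label_volume()]s of identical shape.
#' @return An object of class `overlap_table`: list with `pairs` (data.frame
#'   `gt_id`, `pred_id`, `intersection`, sorted by (gt_id, pred_id)),
#'   `gt_sizes` and `pred_sizes` (named integer vectors), and `n_voxels`.
#' @export
overlap_table <- function(gt, pred) {
  stopifnot(inherits(gt, "label_volume"), inherits(pred, "label_volume"))
  if (!identical(dim(gt$grid), dim(pred$grid))) {
    stop("gt and pred shapes differ: ",
         paste(dim(gt$grid), collapse = "x"), " vs ",
         paste(dim(pred$grid), collapse = "x"), call. = FALSE)
  }
  g <- as.vector(gt$grid)
  p <- as.vector(pred$grid)
  gt_sizes <- size_table(g)
  pred_sizes <- size_table(p)
  both <- g > 0L & p > 0L
  if (any(both)) {
    dt <- data.table::data.table(gt_id = g[both], pred_id = p[both])
    pairs <- as.data.frame(
      dt[, list(intersection = .N), by = c("gt_id", "pred_id")]
    )
    pairs <- pairs[order(pairs$gt_id, pairs$pred_id), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(gt_id = integer(), pred_id = integer(),
                        intersection = integer())
  }
  structure(list(pairs = pairs, gt_sizes = gt_sizes, pred_sizes = pred_sizes,
                 n_voxels = length(g)),
            class = "overlap_table")
}

size_table <- function(v) {
  v <- v[v > 0L]
  if (!length(v)) return(setNames(integer(), character()))
  tab <- table(v)
  setNames(as.integer(tab), names(tab))
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("<overlap_table> %d GT x %d predicted instances, %d overlapping pairs\n",
              length(x$gt_sizes), length(x$pred_sizes), nrow(x$pairs)))
  invisible(x)
}

#' Intersection-over-union of one (gt, pred) instance pair
#'
#' IoU(A, B) = |A intersect B| / |A union B|, computed lazily from the
#' overlap table counts. Pairs absent from the table have IoU 0.
#'
#' @param table an [overlap_table()].
#' @param g,p a ground-truth and a predicted instance id.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(table, g, p) {
  stopifnot(inherits(table, "overlap_table"))
  gs <- table$gt_sizes[as.character(g)]
  ps <- table$pred_sizes[as.character(p)]
  if (is.na(gs)) stop("unknown gt id: ", g, call. = FALSE)
  if (is.na(ps)) stop("unknown pred id: ", p, call. = FALSE)
  hit <- table$pairs$gt_id == g & table$pairs$pred_id == p
  inter <- if (any(hit)) table$pairs$intersection[hit][1] else 0L
  as.numeric(inter) / (as.numeric(gs) + as.numeric(ps) - inter)
}

#' All overlapping pairs with their IoU
#'
#' @param table an [overlap_table()].
#' @return The `pairs` data.frame with added `gt_size`, `pred_size` and
#'   `iou` columns.
#' @export
iou_pairs <- function(table) {
  stopifnot(inherits(table, "overlap_table"))
  pr <- table$pairs
  pr$gt_size <- as.integer(table$gt_sizes[as.character(pr$gt_id)])
  pr$pred_size <- as.integer(table$pred_sizes[as.character(pr$pred_id)])
  pr$iou <- pr$intersection /
    (as.numeric(pr$gt_size) + as.numeric(pr$pred_size) - pr$intersection)
  pr
}

#' Dump an overlap table to CSV
#'
#' Columns: gt_id, pred_id, intersection, gt_size, pred_size, iou.
#'
#' @param table an [overlap_table()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_overlap_csv <- function(table, path) {
  write.csv(iou_pairs(table), path, row.names = FALSE)
  invisible(path)
}
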