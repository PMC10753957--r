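#' Rank predicted instances by size-as-confidence
#'
#' Bottom-up watershed decoders emit no detection confidence, so instance
#' voxel count is used as a confidence proxy: larger instances rank first.
#' Ties are broken by ascending id.
#'
#' @param index an [instance_index][build_index] of the prediction.
#' @return Integer vector of pred ids in descending-confidence order.
#' @export
rank_by_size <- function(index) {
  stopifnot(inherits(index, "instance_index"))
  if (!length(index$ids)) return(integer())
  sz <- index$sizes[as.character(index$ids)]
  index$ids[order(-as.numeric(sz), index$ids)]
}

#' Precision-recall curve under greedy rank-order matching
#'
#' Predictions are consumed in confidence order; each matches the
#' highest-IoU still-unmatched ground-truth instance provided IoU >= T
#' (a true positive), otherwise it is a false positive (equal-IoU ties go
#' to the lowest gt id). Precision and recall are accumulated after every
#' prediction. This greedy matcher is the standard AP semantics; the
#' Hungarian matcher is used only for the accuracy metric.
#'
#' @param ranked pred ids in confidence order, from [rank_by_size()].
#' @param table an [overlap_table()].
#' @param T IoU threshold in (0, 1].
#' @param n_gt number of ground-truth instances over which recall is
#'   measured (defaults to the table's GT count).
#' @return A `pr_curve`: data.frame with `pred_id`, `tp`, `precision`,
#'   `recall` (one row per prediction, in rank order), with `n_gt` as an
#'   attribute.
#' @export
pr_curve <- function(ranked, table, T = 0.75, n_gt = length(table$gt_sizes)) {
  stopifnot(inherits(table, "overlap_table"))
  if (!(T > 0 && T <= 1)) stop("T must lie in (0, 1]", call. = FALSE)
  pr <- iou_pairs(table)
  matched_gt <- integer()
  tp <- logical(length(ranked))
  for (k in seq_along(ranked)) {
    cand <- pr[pr$pred_id == ranked[k] & pr$iou >= T &
                 !(pr$gt_id %in% matched_gt), , drop = FALSE]
    if (nrow(cand)) {
      cand <- cand[order(-cand$iou, cand$gt_id), , drop = FALSE]
      matched_gt <- c(matched_gt, cand$gt_id[1])
      tp[k] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  out <- data.frame(pred_id = ranked, tp = tp,
                    precision = if (length(ranked)) {
                      cum_tp / seq_along(ranked)
                    } else numeric(),
                    recall = if (length(ranked)) {
                      if (n_gt > 0) cum_tp / n_gt else rep(0, length(ranked))
                    } else numeric())
  structure(out, n_gt = n_gt, class = c("pr_curve", "data.frame"))
}

# max precision at recall >= r, 0 when that recall is never reached
interp_precision <- function(curve, r) {
  ok <- curve$recall >= r - 1e-12
  if (!any(ok)) return(0)
  max(curve$precision[ok])
}

#' 11-point interpolated average precision
#'
#' AP = mean of the interpolated precision at the eleven recall levels
#' 0, 0.1, ..., 1, where the interpolated precision at recall r is the
#' maximum measured precision at any recall >= r (0 if that recall is
#' never reached).
#'
#' @param curve a [pr_curve()].
#' @return AP in \[0, 1\].
#' @export
ap_11point <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  mean(vapply(seq(0, 1, by = 0.1), function(r) interp_precision(curve, r),
              numeric(1)))
}

#' All-point (integral) average precision
#'
#' Diagnostic variant: the exact area under the interpolated
#' precision-recall curve rather than the 11-point approximation.
#'
#' @param curve a [pr_curve()].
#' @return AP in \[0, 1\].
#' @export
ap_allpoint <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  rec <- c(0, curve$recall)
  out <- 0
  for (k in seq_len(nrow(curve))) {
    dr <- rec[k + 1] - rec[k]
    if (dr > 0) out <- out + dr * interp_precision(curve, rec[k + 1])
  }
  out
}

# AP for a subset of instances: restrict the table to the given id sets
subset_table <- function(table, gt_keep, pred_keep) {
  pairs <- table$pairs[table$pairs$gt_id %in% gt_keep &
                         table$pairs$pred_id %in% pred_keep, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 gt_sizes = table$gt_sizes[as.character(gt_keep)],
                 pred_sizes = table$pred_sizes[as.character(pred_keep)],
                 n_voxels = table$n_voxels),
            class = "overlap_table")
}

#' AP-75 report, overall and per size group
#'
#' Computes the 11-point AP at T = 0.75 (size-as-confidence, greedy
#' rank-order matching) over all instances, and restricted to each size
#' group. The per-group computation keeps only ground-truth and predicted
#' instances of that group (the prediction's group comes from its own
#' mask), which reproduces the behavior that a small instance merged into a
#' larger prediction counts as a small false negative.
#'
#' @param gt,pred [label_volume()]s.
#' @param gt_grouping,pred_grouping [size groupings][group_by_length] of the
#'   two volumes.
#' @param T IoU threshold, default 0.75.
#' @param table optional precomputed [overlap_table()].
#' @return data.frame with `scope`, `ap`, `n_gt`, `n_pred`, `empty` (TRUE
#'   when a group has no ground truth and no predictions).
#' @export
ap75_report <- function(gt = NULL, pred = NULL, gt_grouping = NULL,
                        pred_grouping = NULL, T = 0.75, table = NULL) {
  if (is.null(table)) table <- overlap_table(gt, pred)
  pred_ids <- as.integer(names(table$pred_sizes))
  gt_ids <- as.integer(names(table$gt_sizes))
  ap_of <- function(tab) {
    idx <- structure(list(ids = as.integer(names(tab$pred_sizes)),
                          sizes = tab$pred_sizes, bbox = NULL),
                     class = "instance_index")
    curve <- pr_curve(rank_by_size(idx), tab, T,
                      n_gt = length(tab$gt_sizes))
    if (length(tab$gt_sizes) == 0 || length(tab$pred_sizes) == 0) {
      return(0)
    }
    ap_11point(curve)
  }
  rows <- data.frame(scope = "total", ap = ap_of(table),
                     n_gt = length(gt_ids), n_pred = length(pred_ids),
                     empty = length(gt_ids) == 0 && length(pred_ids) == 0)
  if (!is.null(gt_grouping)) {
    if (is.null(pred_grouping)) {
      stop("per-group AP needs both gt and pred groupings", call. = FALSE)
    }
    g_of_gt <- grouping_lookup(gt_grouping)
    g_of_pred <- grouping_lookup(pred_grouping)
    for (grp in c("small", "medium", "large")) {
      gk <- gt_ids[g_of_gt[as.character(gt_ids)] == grp]
      pk <- pred_ids[g_of_pred[as.character(pred_ids)] == grp]
      tab <- subset_table(table, gk, pk)
      rows <- rbind(rows, data.frame(scope = grp, ap = ap_of(tab),
                                     n_gt = length(gk), n_pred = length(pk),
                                     empty = !length(gk) && !length(pk)))
    }
  }
  rows
}
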