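#' Assignment cost matrix for Hungarian matching
#'
#' One row per predicted instance p_i, one column per ground-truth instance
#' g_j, with cost
#' \deqn{C(i,j) = -[IoU(g_j, p_i) \ge T] - IoU(g_j, p_i) / (2N)}
#' where N = min(#pred, #gt). The indicator term dominates (the IoU term is
#' strictly below 1/2), so the optimal assignment maximizes the number of
#' supra-threshold matches and uses IoU only to break ties among
#' equal-indicator alternatives. Zero-overlap pairs cost 0.
#'
#' @param table an [overlap_table()].
#' @param T IoU threshold in (0, 1]; 0.75 is the AP-75 convention.
#' @return A `cost_matrix`: numeric matrix with pred ids as rownames and gt
#'   ids as colnames, attributes `T`, `N` and `iou` (the matching IoU
#'   matrix).
#' @export
build_cost_matrix <- function(table, T = 0.75) {
  stopifnot(inherits(table, "overlap_table"))
  if (!(T > 0 && T <= 1)) stop("T must lie in (0, 1]", call. = FALSE)
  pred_ids <- as.integer(names(table$pred_sizes))
  gt_ids <- as.integer(names(table$gt_sizes))
  if (!length(pred_ids) || !length(gt_ids)) {
    stop("cost matrix needs at least one instance on each side",
         call. = FALSE)
  }
  N <- min(length(pred_ids), length(gt_ids))
  pr <- iou_pairs(table)
  iou_m <- matrix(0, length(pred_ids), length(gt_ids),
                  dimnames = list(pred_ids, gt_ids))
  if (nrow(pr)) {
    iou_m[cbind(match(pr$pred_id, pred_ids), match(pr$gt_id, gt_ids))] <-
      pr$iou
  }
  cost <- -(iou_m >= T) - iou_m / (2 * N)
  structure(cost, T = T, N = N, iou = iou_m, class = "cost_matrix")
}

#' Optimal one-to-one assignment between predictions and ground truth
#'
#' Solves the linear sum assignment problem for the cost of
#' [build_cost_matrix()] (Hungarian method via [clue::solve_LSAP()]), so no
#' instance is assigned to more than one partner. Assigned pairs with IoU
#' >= T are true positives; every other predicted instance is a false
#' positive and every other ground-truth instance a false negative.
#'
#' @param cost a `cost_matrix` from [build_cost_matrix()].
#' @return A `match_result`: list with `assignment` (data.frame `gt_id`,
#'   `pred_id`, `iou` for assigned pairs with positive overlap), `tp_pairs`
#'   (subset with IoU >= T), `fp_pred_ids`, `fn_gt_ids`, `T`, `n_gt`,
#'   `n_pred`.
#' @export
optimal_assignment <- function(cost) {
  stopifnot(inherits(cost, "cost_matrix"))
  T <- attr(cost, "T")
  iou_m <- attr(cost, "iou")
  pred_ids <- as.integer(rownames(cost))
  gt_ids <- as.integer(colnames(cost))
  x <- unclass(cost)
  attributes(x) <- list(dim = dim(cost))
  # solve_LSAP needs non-negative entries and nrow <= ncol; shifting all
  # entries by a constant never changes the optimizer on a padded square
  transposed <- nrow(x) > ncol(x)
  if (transposed) x <- t(x)
  sol <- clue::solve_LSAP(x - min(x), maximum = FALSE)
  rows <- seq_len(nrow(x))
  cols <- as.integer(sol)
  if (transposed) {
    pi <- cols
    gi <- rows
  } else {
    pi <- rows
    gi <- cols
  }
  keep <- iou_m[cbind(pi, gi)] > 0
  assignment <- data.frame(gt_id = gt_ids[gi[keep]],
                           pred_id = pred_ids[pi[keep]],
                           iou = iou_m[cbind(pi, gi)][keep])
  assignment <- assignment[order(assignment$gt_id), , drop = FALSE]
  rownames(assignment) <- NULL
  tp <- assignment[assignment$iou >= T, , drop = FALSE]
  rownames(tp) <- NULL
  structure(list(assignment = assignment,
                 tp_pairs = tp,
                 fp_pred_ids = setdiff(pred_ids, tp$pred_id),
                 fn_gt_ids = setdiff(gt_ids, tp$gt_id),
                 T = T,
                 n_gt = length(gt_ids),
                 n_pred = length(pred_ids)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> T = %.2f: TP %d, FP %d, FN %d\n", x$T,
              nrow(x$tp_pairs), length(x$fp_pred_ids), length(x$fn_gt_ids)))
  invisible(x)
}

#' Hungarian matching of two label volumes
#'
#' Convenience wrapper: builds the overlap table (or takes one), the Eq.-style
#' cost matrix, and solves the assignment. Degenerate inputs (no instances
#' on a side) yield the trivial result with an empty assignment.
#'
#' @param gt,pred [label_volume()]s, or pass a precomputed table via
#'   `table`.
#' @param T IoU threshold, default 0.75.
#' @param table optional [overlap_table()] (then `gt`/`pred` are ignored).
#' @return A `match_result` (see [optimal_assignment()]).
#' @export
hungarian_match <- function(gt = NULL, pred = NULL, T = 0.75, table = NULL) {
  if (is.null(table)) table <- overlap_table(gt, pred)
  n_gt <- length(table$gt_sizes)
  n_pred <- length(table$pred_sizes)
  if (n_gt == 0L || n_pred == 0L) {
    empty <- data.frame(gt_id = integer(), pred_id = integer(),
                        iou = numeric())
    return(structure(list(assignment = empty, tp_pairs = empty,
                          fp_pred_ids = as.integer(names(table$pred_sizes)),
                          fn_gt_ids = as.integer(names(table$gt_sizes)),
                          T = T, n_gt = n_gt, n_pred = n_pred),
                     class = "match_result"))
  }
  optimal_assignment(build_cost_matrix(table, T))
}

ratio0 <- function(num, den) if (den > 0) num / den else 0

#' Matching-based precision, recall and accuracy
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN) and
#' accuracy = TP/(TP+FP+FN), overall and (when groupings are supplied) per
#' size group. TP and FN are binned by the ground-truth instance's group;
#' FP are binned by the predicted instance's own group by default
#' (`fp_by = "pred"`), or by the best-overlapping ground-truth instance's
#' group (`fp_by = "matched_gt"`, falling back to the prediction's own
#' group for background predictions). A 0/0 ratio is reported as 0.
#'
#' @param match a `match_result`.
#' @param gt_grouping,pred_grouping optional [size groupings][group_by_length]
#'   covering the ground-truth and predicted instances.
#' @param fp_by `"pred"` or `"matched_gt"`; see Details.
#' @param table overlap table, required only for `fp_by = "matched_gt"`.
#' @return data.frame with columns `scope`, `TP`, `FP`, `FN`, `precision`,
#'   `recall`, `accuracy`; first row is the overall scope.
#' @export
matching_scores <- function(match, gt_grouping = NULL, pred_grouping = NULL,
                            fp_by = c("pred", "matched_gt"), table = NULL) {
  stopifnot(inherits(match, "match_result"))
  fp_by <- match.arg(fp_by)
  tp_n <- nrow(match$tp_pairs)
  rows <- data.frame(scope = "total", TP = tp_n,
                     FP = length(match$fp_pred_ids),
                     FN = length(match$fn_gt_ids))
  if (!is.null(gt_grouping)) {
    if (is.null(pred_grouping)) {
      stop("per-group scores need both gt and pred groupings", call. = FALSE)
    }
    g_of_gt <- grouping_lookup(gt_grouping)
    g_of_pred <- grouping_lookup(pred_grouping)
    all_gt <- c(match$tp_pairs$gt_id, match$fn_gt_ids)
    if (anyNA(g_of_gt[as.character(all_gt)])) {
      stop("gt grouping does not cover all ground-truth ids", call. = FALSE)
    }
    fp_ids <- match$fp_pred_ids
    if (fp_by == "pred") {
      fp_grp <- g_of_pred[as.character(fp_ids)]
    } else {
      if (is.null(table)) {
        stop("fp_by = 'matched_gt' requires the overlap table", call. = FALSE)
      }
      pr <- iou_pairs(table)
      fp_grp <- vapply(fp_ids, function(p) {
        cand <- pr[pr$pred_id == p, , drop = FALSE]
        if (!nrow(cand)) return(g_of_pred[as.character(p)])
        best <- cand$gt_id[which.max(cand$iou)]
        g_of_gt[as.character(best)]
      }, character(1))
    }
    if (anyNA(fp_grp)) {
      stop("pred grouping does not cover all predicted ids", call. = FALSE)
    }
    for (grp in c("small", "medium", "large")) {
      rows <- rbind(rows, data.frame(
        scope = grp,
        TP = sum(g_of_gt[as.character(match$tp_pairs$gt_id)] == grp),
        FP = sum(fp_grp == grp),
        FN = sum(g_of_gt[as.character(match$fn_gt_ids)] == grp)))
    }
  }
  rows$precision <- mapply(function(tp, fp) ratio0(tp, tp + fp),
                           rows$TP, rows$FP)
  rows$recall <- mapply(function(tp, fn) ratio0(tp, tp + fn),
                        rows$TP, rows$FN)
  rows$accuracy <- mapply(function(tp, fp, fn) ratio0(tp, tp + fp + fn),
                          rows$TP, rows$FP, rows$FN)
  rows
}
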