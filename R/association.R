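#' Association graph between predicted and ground-truth instances
#'
#' The set A of associated pairs: every (pred, gt) pair whose intersection
#' reaches `min_overlap` voxels (default 1, i.e. any positive overlap).
#' A(g) is the set of predictions associated with ground-truth instance g;
#' A'(p) the set of ground-truth instances associated with prediction p.
#' `min_overlap` is exposed because single-voxel touches can inflate the
#' many-to-many class on noisy decoders; the default keeps the strict
#' any-overlap definition.
#'
#' @param table an [overlap_table()].
#' @param min_overlap minimum intersection voxel count for a pair to count
#'   as associated.
#' @return An `association_graph`: list with `pairs` (data.frame `pred_id`,
#'   `gt_id`, `intersection`), `A_of_g` and `A_of_p` (named lists of id
#'   vectors), `gt_ids`, `pred_ids`.
#' @export
association_graph <- function(table, min_overlap = 1L) {
  stopifnot(inherits(table, "overlap_table"))
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)
  keep <- table$pairs$intersection >= min_overlap
  pairs <- table$pairs[keep, c("pred_id", "gt_id", "intersection"),
                       drop = FALSE]
  rownames(pairs) <- NULL
  gt_ids <- as.integer(names(table$gt_sizes))
  pred_ids <- as.integer(names(table$pred_sizes))
  A_of_g <- lapply(setNames(gt_ids, gt_ids), function(g) {
    sort(pairs$pred_id[pairs$gt_id == g])
  })
  A_of_p <- lapply(setNames(pred_ids, pred_ids), function(p) {
    sort(pairs$gt_id[pairs$pred_id == p])
  })
  structure(list(pairs = pairs, A_of_g = A_of_g, A_of_p = A_of_p,
                 gt_ids = gt_ids, pred_ids = pred_ids),
            class = "association_graph")
}

#' Six-way association taxonomy
#'
#' Categorizes every ground-truth instance g by its reciprocal mapping:
#' * `missing`: A(g) is empty;
#' * `one_to_one`: A(g) = \{p\} and A'(p) = \{g\};
#' * `over_segmentation`: |A(g)| > 1 and every p in A(g) has A'(p) = \{g\};
#' * `under_segmentation`: A(g) = \{p\}, |A'(p)| > 1, and every g' in A'(p)
#'   has A(g') = \{p\} (each merged ground-truth instance receives the
#'   label);
#' * `many_to_many`: all other cases.
#'
#' Predictions with A'(p) empty are `background` (false positives).
#'
#' @param graph an [association_graph()].
#' @return An `association_result`: list with `gt_category` (data.frame
#'   `gt_id`, `category`, `n_assoc`), `background_preds` (integer ids),
#'   `n_gt`, `n_pred`, and the originating `graph`.
#' @export
categorize_associations <- function(graph) {
  stopifnot(inherits(graph, "association_graph"))
  deg_p <- vapply(graph$A_of_p, length, integer(1))
  cat_of <- vapply(as.character(graph$gt_ids), function(g) {
    Ag <- graph$A_of_g[[g]]
    if (!length(Ag)) return("missing")
    if (length(Ag) == 1L) {
      p <- as.character(Ag)
      Ap <- graph$A_of_p[[p]]
      if (length(Ap) == 1L) return("one_to_one")
      # g has one partner p that merges several gt: under-segmentation
      # only if the merge is exclusive on both sides
      pure <- all(vapply(as.character(Ap), function(g2) {
        identical(graph$A_of_g[[g2]], Ag)
      }, logical(1)))
      return(if (pure) "under_segmentation" else "many_to_many")
    }
    pure <- all(vapply(as.character(Ag), function(p) {
      length(graph$A_of_p[[p]]) == 1L
    }, logical(1)))
    if (pure) "over_segmentation" else "many_to_many"
  }, character(1))
  gt_category <- data.frame(
    gt_id = graph$gt_ids,
    category = unname(cat_of),
    n_assoc = vapply(as.character(graph$gt_ids),
                     function(g) length(graph$A_of_g[[g]]), integer(1)))
  rownames(gt_category) <- NULL
  structure(list(gt_category = gt_category,
                 background_preds = graph$pred_ids[deg_p == 0L],
                 n_gt = length(graph$gt_ids),
                 n_pred = length(graph$pred_ids),
                 graph = graph),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  tab <- table(factor(x$gt_category$category, levels = association_levels()))
  cat("<association_result>", x$n_gt, "GT /", x$n_pred, "pred instances\n")
  print(tab)
  cat("background predictions:", length(x$background_preds), "\n")
  invisible(x)
}

association_levels <- function() {
  c("one_to_one", "over_segmentation", "under_segmentation",
    "many_to_many", "missing")
}

#' Association percentages, overall and per size group
#'
#' Non-background categories are expressed as a percentage of the number
#' of ground-truth instances (per group: of the group's ground-truth
#' count), so they sum to 100. The background category uses the number of
#' predicted instances as denominator and is reported overall only (an
#' opt-in per-predicted-group breakdown is available via
#' `background_by_group` with a prediction grouping).
#'
#' @param result an [categorize_associations()] result.
#' @param grouping optional [size grouping][group_by_length] of the
#'   ground-truth instances.
#' @param background_by_group optional prediction grouping; adds per-group
#'   background rows.
#' @return data.frame with `scope`, `category`, `count`, `denominator`,
#'   `percent`.
#' @export
association_percentages <- function(result, grouping = NULL,
                                    background_by_group = NULL) {
  stopifnot(inherits(result, "association_result"))
  lv <- association_levels()
  pct_rows <- function(scope, ids, denom) {
    cats <- result$gt_category$category[result$gt_category$gt_id %in% ids]
    counts <- as.integer(table(factor(cats, levels = lv)))
    data.frame(scope = scope, category = lv, count = counts,
               denominator = denom,
               percent = if (denom > 0) 100 * counts / denom else 0)
  }
  out <- pct_rows("total", result$gt_category$gt_id, result$n_gt)
  out <- rbind(out, data.frame(scope = "total", category = "background",
                               count = length(result$background_preds),
                               denominator = result$n_pred,
                               percent = if (result$n_pred > 0) {
                                 100 * length(result$background_preds) /
                                   result$n_pred
                               } else 0))
  if (!is.null(grouping)) {
    g_of <- grouping_lookup(grouping)
    gt_ids <- result$gt_category$gt_id
    if (anyNA(g_of[as.character(gt_ids)])) {
      stop("grouping does not cover all ground-truth ids", call. = FALSE)
    }
    for (grp in c("small", "medium", "large")) {
      ids <- gt_ids[g_of[as.character(gt_ids)] == grp]
      out <- rbind(out, pct_rows(grp, ids, length(ids)))
    }
    if (!is.null(background_by_group)) {
      p_of <- grouping_lookup(background_by_group)
      bg <- result$background_preds
      for (grp in c("small", "medium", "large")) {
        n_grp <- sum(p_of == grp)
        cnt <- sum(p_of[as.character(bg)] == grp, na.rm = TRUE)
        out <- rbind(out, data.frame(
          scope = grp, category = "background", count = cnt,
          denominator = n_grp,
          percent = if (n_grp > 0) 100 * cnt / n_grp else 0))
      }
    }
  }
  rownames(out) <- NULL
  out
}
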