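#' Evaluation configuration
#'
#' @param iou_threshold IoU threshold T for matching and AP (default 0.75).
#' @param grouping `"length"` (cable length) or `"volume"`.
#' @param length_thresholds_um small/large cable-length cutoffs in um.
#' @param volume_thresholds voxel cutoffs for volume grouping (required in
#'   that mode).
#' @param min_overlap_voxels minimum intersection for an association pair.
#' @param nbins number of cable-length bins for the split/merge histogram.
#' @param fp_by how false positives are binned per group: `"pred"` (the
#'   prediction's own group) or `"matched_gt"`.
#' @param spacing_nm optional spacing override applied to both volumes.
#' @return An `eval_config` list.
#' @export
eval_config <- function(iou_threshold = 0.75,
                        grouping = c("length", "volume"),
                        length_thresholds_um = c(1, 4),
                        volume_thresholds = NULL,
                        min_overlap_voxels = 1L,
                        nbins = 15L,
                        fp_by = c("pred", "matched_gt"),
                        spacing_nm = NULL) {
  grouping <- match.arg(grouping)
  fp_by <- match.arg(fp_by)
  if (!(iou_threshold > 0 && iou_threshold <= 1)) {
    stop("iou_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (grouping == "volume" && is.null(volume_thresholds)) {
    stop("volume grouping requires explicit volume_thresholds",
         call. = FALSE)
  }
  structure(list(iou_threshold = iou_threshold, grouping = grouping,
                 length_thresholds_um = as.numeric(length_thresholds_um),
                 volume_thresholds = volume_thresholds,
                 min_overlap_voxels = as.integer(min_overlap_voxels),
                 nbins = as.integer(nbins), fp_by = fp_by,
                 spacing_nm = spacing_nm),
            class = "eval_config")
}

#' Full metric panel for a (ground truth, prediction) pair
#'
#' Runs the complete evaluation pipeline on one shared overlap table:
#' size grouping of both volumes, Hungarian matching scores (precision /
#' recall / accuracy, overall and per group), AP-75 (overall and per
#' group), the association taxonomy with its percentages, and the
#' split/merger decomposition with the cable-length histogram.
#'
#' @param gt,pred [label_volume()]s of identical shape.
#' @param config an [eval_config()].
#' @return A `metrics_report`: list with `scores`, `ap`, `association`,
#'   `split_merge` (list `summary`, `histogram`), `grouping` (list `gt`,
#'   `pred`), `counts` and `provenance`.
#' @export
evaluate <- function(gt, pred, config = eval_config()) {
  stopifnot(inherits(gt, "label_volume"), inherits(pred, "label_volume"),
            inherits(config, "eval_config"))
  if (!is.null(config$spacing_nm)) {
    gt$spacing <- pred$spacing <- as.numeric(config$spacing_nm)
  }
  if (!identical(dim(gt$grid), dim(pred$grid))) {
    stop("[volumes] gt and pred shapes differ", call. = FALSE)
  }
  table <- overlap_table(gt, pred)
  gt_index <- build_index(gt)
  pred_index <- build_index(pred)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  gt_lengths <- NULL
  if (config$grouping == "length") {
    gt_lengths <- stage("morphology", cable_lengths(gt, gt_index))
    gt_grouping <- stage("morphology", group_by_length(
      gt_lengths, config$length_thresholds_um))
    pred_grouping <- stage("morphology", group_by_length(
      cable_lengths(pred, pred_index), config$length_thresholds_um))
  } else {
    gt_grouping <- stage("morphology", group_by_volume(
      gt_index$sizes, config$volume_thresholds))
    pred_grouping <- stage("morphology", group_by_volume(
      pred_index$sizes, config$volume_thresholds))
  }
  has_both <- length(gt_index$ids) > 0 && length(pred_index$ids) > 0
  match <- stage("matching", hungarian_match(table = table,
                                             T = config$iou_threshold))
  scores <- stage("matching", matching_scores(
    match, gt_grouping = gt_grouping, pred_grouping = pred_grouping,
    fp_by = config$fp_by, table = table))
  ap <- stage("ap", ap75_report(gt_grouping = gt_grouping,
                                pred_grouping = pred_grouping,
                                T = config$iou_threshold, table = table))
  graph <- stage("association",
                 association_graph(table, config$min_overlap_voxels))
  categories <- stage("association", categorize_associations(graph))
  assoc <- stage("association",
                 association_percentages(categories, grouping = gt_grouping))
  record <- stage("morphology", split_merge_sets(graph, categories))
  hist <- NULL
  if (config$grouping == "length" && length(gt_lengths)) {
    hist <- stage("morphology",
                  split_merge_histogram(record, gt_lengths, config$nbins))
  }
  structure(list(
    scores = scores,
    ap = ap,
    association = assoc,
    association_categories = categories$gt_category,
    split_merge = list(
      summary = data.frame(
        n_split_pairs = nrow(record$S),
        n_split_gt = length(record$splits_per_gt),
        n_merge_pairs = nrow(record$M),
        n_merge_pred = length(record$merges_per_pred)),
      histogram = hist),
    grouping = list(gt = gt_grouping, pred = pred_grouping),
    counts = list(n_gt = length(gt_index$ids),
                  n_pred = length(pred_index$ids),
                  n_voxels = table$n_voxels),
    provenance = list(
      config = unclass(config),
      spacing_nm = gt$spacing,
      shape = dim(gt$grid),
      package_version = as.character(utils::packageVersion("mitometrics")),
      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", x$counts$n_gt, "GT /", x$counts$n_pred,
      "predicted instances\n\nMatching scores:\n")
  sc <- x$scores
  sc$precision <- round(sc$precision, 3)
  sc$recall <- round(sc$recall, 3)
  sc$accuracy <- round(sc$accuracy, 3)
  print(sc, row.names = FALSE)
  cat("\nAP-75:\n")
  ap <- x$ap
  ap$ap <- round(ap$ap, 3)
  print(ap, row.names = FALSE)
  cat("\nAssociation (% of GT; background % of predictions):\n")
  as_tab <- x$association
  as_tab$percent <- round(as_tab$percent, 1)
  print(as_tab[, c("scope", "category", "count", "percent")],
        row.names = FALSE)
  invisible(x)
}

report_tables <- function(report) {
  list(scores = report$scores, ap = report$ap,
       association = report$association,
       split_summary = report$split_merge$summary,
       split_histogram = report$split_merge$histogram)
}

#' Write a metrics report to disk
#'
#' JSON keeps full precision and is lossless for every reported number;
#' CSV and markdown are human-oriented formatted views (markdown rounds
#' percentages to one decimal, matching the usual table style).
#'
#' @param report a [evaluate()] result.
#' @param path destination path.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "markdown")) {
  stopifnot(inherits(report, "metrics_report"))
  format <- match.arg(format)
  if (format == "json") {
    out <- list(scores = report$scores, ap = report$ap,
                association = report$association,
                association_categories = report$association_categories,
                split_merge = report$split_merge,
                grouping = list(gt = as.data.frame(report$grouping$gt),
                                pred = as.data.frame(report$grouping$pred)),
                counts = report$counts,
                provenance = report$provenance)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "columns")
  } else if (format == "csv") {
    tabs <- report_tables(report)
    rows <- do.call(rbind, lapply(names(tabs), function(nm) {
      t <- tabs[[nm]]
      if (is.null(t) || !nrow(t)) return(NULL)
      data.frame(table = nm, row = seq_len(nrow(t)),
                 field = rep(names(t), each = nrow(t)),
                 value = as.character(unlist(t, use.names = FALSE)))
    }))
    write.csv(rows, path, row.names = FALSE)
  } else {
    lines <- c("# Segmentation evaluation report", "",
               "## Matching scores", md_table(transform(
                 report$scores,
                 precision = sprintf("%.3f", precision),
                 recall = sprintf("%.3f", recall),
                 accuracy = sprintf("%.3f", accuracy))),
               "", "## AP-75", md_table(transform(
                 report$ap, ap = sprintf("%.3f", ap))),
               "", "## Association (%)", md_table(transform(
                 report$association, percent = sprintf("%.1f", percent))))
    writeLines(lines, path)
  }
  invisible(path)
}

md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Read back a JSON metrics report
#'
#' @param path a JSON file written by [write_report()].
#' @return The parsed report as a list of data.frames and lists.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
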