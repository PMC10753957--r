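# Independent oracles: deliberately naive reimplementations used to verify
# the package's fast paths on small inputs.

# all permutations of a vector (n! rows); fine for n <= 6
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# exhaustive minimum assignment cost for an n x m cost matrix, where every
# row (if n <= m) or every column (if m < n) must be assigned
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  best <- Inf
  if (n <= m) {
    for (p in all_perms(seq_len(m))) {
      best <- min(best, sum(cost[cbind(seq_len(n), p[seq_len(n)])]))
    }
  } else {
    for (p in all_perms(seq_len(n))) {
      best <- min(best, sum(cost[cbind(p[seq_len(m)], seq_len(m))]))
    }
  }
  best
}

# per-voxel double-loop overlap table: compare every gt/pred id pair by
# scanning the full grids
brute_force_overlap <- function(gt, pred) {
  g_ids <- sort(unique(as.vector(gt$grid)))
  p_ids <- sort(unique(as.vector(pred$grid)))
  g_ids <- g_ids[g_ids > 0]
  p_ids <- p_ids[p_ids > 0]
  rows <- list()
  for (g in g_ids) {
    for (p in p_ids) {
      inter <- sum(gt$grid == g & pred$grid == p)
      if (inter > 0) {
        rows[[length(rows) + 1L]] <-
          data.frame(gt_id = g, pred_id = p, intersection = inter)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gt_id = integer(), pred_id = integer(),
                      intersection = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$gt_id, out$pred_id), , drop = FALSE]
}

# scripted re-evaluation of 11-point AP from a ranked TP/FP sequence
oracle_ap_11point <- function(tp, n_gt) {
  if (!length(tp) || n_gt == 0) return(0)
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / n_gt
  mean(vapply(seq(0, 1, 0.1), function(r) {
    ok <- rec >= r - 1e-12
    if (!any(ok)) 0 else max(prec[ok])
  }, numeric(1)))
}

# greedy rank-order matching re-simulated directly on the volumes
oracle_greedy_tp <- function(gt, pred, ranked, T) {
  used <- integer()
  tp <- logical(length(ranked))
  for (k in seq_along(ranked)) {
    p_mask <- pred$grid == ranked[k]
    g_ids <- setdiff(sort(unique(gt$grid[p_mask])), c(0, used))
    best_iou <- 0
    best_g <- NA
    for (g in g_ids) {
      g_mask <- gt$grid == g
      i <- sum(p_mask & g_mask) / sum(p_mask | g_mask)
      if (i > best_iou + 1e-12) {
        best_iou <- i
        best_g <- g
      }
    }
    if (!is.na(best_g) && best_iou >= T) {
      used <- c(used, best_g)
      tp[k] <- TRUE
    }
  }
  tp
}

# brute-force sliding-window median over the (z, y) plane of each x slice
oracle_median_yz <- function(arr, radius) {
  d <- dim(arr)
  out <- array(0, d)
  for (x in seq_len(d[3])) {
    for (y in seq_len(d[2])) {
      for (z in seq_len(d[1])) {
        zi <- max(1, z - radius):min(d[1], z + radius)
        yi <- max(1, y - radius):min(d[2], y + radius)
        out[z, y, x] <- median(arr[zi, yi, x])
      }
    }
  }
  out
}

# a tiny deterministic two-instance volume used across tests
tiny_pair <- function() {
  g <- array(0L, c(4, 6, 6))
  g[2:3, 2:3, 2:3] <- 1L
  g[2:3, 5:6, 5:6] <- 2L
  label_volume(g, c(30, 8, 8))
}

# random gt/pred pair with overlapping supports for matching tests
random_pair <- function(seed, n_max = 5L, shape = c(8L, 10L, 10L)) {
  k1 <- 2L + (seed %% (n_max - 1L))
  k2 <- 2L + ((seed * 7L) %% (n_max - 1L))
  list(gt = random_scene(k1, shape = shape, size_range = c(2, 4),
                         seed = seed),
       pred = random_scene(k2, shape = shape, size_range = c(2, 4),
                           seed = seed + 10000L))
}
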