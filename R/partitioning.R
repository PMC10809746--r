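#' Partitioning configuration
#'
#' Parameters for the recursive BIRCH-style partitioning of anchor-distance
#' vectors. Defaults follow the package-wide defaults: merge radius 0.5 on the
#' normalized-distance scale, leaf size threshold 1000 sequences, and model
#' fitting on a 10% subsample for large groups (small groups are fitted in
#' full, see `fit_fraction`).
#'
#' @param radius_threshold Clustering-feature merge radius: a point joins its
#'   nearest subcluster iff the merged subcluster's radius stays at or below
#'   this value; otherwise it opens a new subcluster.
#' @param size_threshold Maximum number of sequences handed to all-pairs
#'   single-linkage clustering; larger groups are partitioned recursively.
#' @param fit_fraction Fraction of rows used to build the clustering-feature
#'   model before assigning all rows; `NULL` (default) uses 1.0 for groups of
#'   at most 10,000 sequences and 0.1 above that.
#' @param packing A [packing_params()] list for anchor selection.
#' @param branching Maximum number of subclusters scanned exactly during
#'   insertion before the model switches to nearest-of-all (kept for
#'   interface compatibility; the flat clustering-feature list scans all).
#' @param max_depth Safety bound on recursion depth; at the bound a group
#'   becomes a forced leaf.
#' @param min_ratio Floor for the automatic fallback that lowers the packing
#'   ratio by 0.1 when too few anchors are found or a split fails; below the
#'   floor the group becomes a forced leaf.
#' @return A list of class `partition_config`.
#' @export
partition_config <- function(radius_threshold = 0.5, size_threshold = 1000,
                             fit_fraction = NULL,
                             packing = packing_params(),
                             branching = 50, max_depth = 30, min_ratio = 0.3) {
  stopifnot(radius_threshold > 0, size_threshold >= 2,
            is.null(fit_fraction) ||
              (fit_fraction > 0 && fit_fraction <= 1),
            max_depth >= 1)
  structure(
    list(radius_threshold = radius_threshold,
         size_threshold = as.integer(size_threshold),
         fit_fraction = fit_fraction,
         packing = packing,
         branching = as.integer(branching),
         max_depth = as.integer(max_depth),
         min_ratio = min_ratio),
    class = "partition_config"
  )
}

# Incremental clustering-feature (CF) model, the core of BIRCH: each
# subcluster is summarized by (n, linear sum, sum of squared norms). A point
# is merged into its nearest subcluster iff the merged radius
# sqrt(SS/n - ||LS/n||^2) stays <= threshold, else it opens a new subcluster.
cf_fit <- function(x, threshold) {
  n <- nrow(x); k <- ncol(x)
  ls <- matrix(0, 64L, k)    # linear sums, grown on demand
  ss <- numeric(64L)         # sums of squared norms
  cnt <- integer(64L)
  m <- 0L
  thr2 <- threshold^2
  for (i in seq_len(n)) {
    xi <- x[i, ]
    xi2 <- sum(xi^2)
    if (m == 0L) {
      m <- 1L; ls[1L, ] <- xi; ss[1L] <- xi2; cnt[1L] <- 1L
      next
    }
    cen <- ls[seq_len(m), , drop = FALSE] / cnt[seq_len(m)]
    d2 <- rowSums(cen^2) - 2 * drop(cen %*% xi) + xi2
    j <- which.min(d2)
    nn <- cnt[j] + 1L
    ls_new <- ls[j, ] + xi
    ss_new <- ss[j] + xi2
    r2 <- ss_new / nn - sum((ls_new / nn)^2)
    if (r2 <= thr2) {
      ls[j, ] <- ls_new; ss[j] <- ss_new; cnt[j] <- nn
    } else {
      m <- m + 1L
      if (m > nrow(ls)) {
        ls <- rbind(ls, matrix(0, nrow(ls), k))
        ss <- c(ss, numeric(length(ss)))
        cnt <- c(cnt, integer(length(cnt)))
      }
      ls[m, ] <- xi; ss[m] <- xi2; cnt[m] <- 1L
    }
  }
  list(centroids = ls[seq_len(m), , drop = FALSE] / cnt[seq_len(m)],
       counts = cnt[seq_len(m)])
}

#' Partition distance vectors with an incremental clustering-feature model
#'
#' Builds the clustering-feature model on a uniform random subsample of
#' `ceil(fit_fraction * n)` rows, agglomerates the resulting subcluster
#' centroids into at most `n_clusters` groups (Ward linkage on the centroid
#' set — the standard BIRCH global step), then assigns *all* rows to the
#' nearest subcluster centroid. Empty parts are dropped and labels are
#' renumbered consecutively.
#'
#' @param vectors Numeric matrix of normalized Hamming distance vectors (rows
#'   = sequences, columns = anchors), e.g. from [batch_distance()].
#' @param n_clusters Target number of parts; by convention the number of
#'   anchors selected by point packing. Clamped to `nrow(vectors)` with a
#'   warning if larger.
#' @param radius Merge radius of the clustering-feature model.
#' @param fit_fraction Fraction of rows used for model fitting, in `(0, 1]`.
#' @return Integer vector of part labels, one per row, labels `1..p` with
#'   `p <= n_clusters`.
#' @export
birch_partition <- function(vectors, n_clusters, radius = 0.5,
                            fit_fraction = 1) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  stopifnot(n >= 1, n_clusters >= 1, fit_fraction > 0, fit_fraction <= 1)
  if (n_clusters > n) {
    warn(sprintf("n_clusters (%d) exceeds number of rows (%d); clamped",
                 n_clusters, n))
    n_clusters <- n
  }
  n_fit <- ceiling(fit_fraction * n)
  fit_rows <- if (n_fit >= n) seq_len(n) else sort(sample.int(n, n_fit))
  model <- cf_fit(vectors[fit_rows, , drop = FALSE], radius)
  m <- nrow(model$centroids)
  sub_lab <- if (m > n_clusters) {
    cutree(hclust(dist(model$centroids), method = "ward.D2"), k = n_clusters)
  } else {
    seq_len(m)
  }
  # nearest-centroid assignment of every row (model frozen after fitting)
  d2 <- outer(rowSums(vectors^2), rowSums(model$centroids^2), "+") -
    2 * tcrossprod(vectors, model$centroids)
  lab <- sub_lab[max.col(-d2, ties.method = "first")]
  as.integer(factor(lab))
}

#' Recursively partition a length stratum into leaf clusters
#'
#' Implements the partitioning loop of the anchor-clustering workflow: a group
#' at or below `size_threshold` is a leaf; otherwise anchors are selected by
#' [evolve_packing()], all sequences are embedded as anchor-distance vectors,
#' the embedding is split with [birch_partition()] (`n_clusters` = number of
#' anchors), and each part is processed recursively. If packing yields fewer
#' than two anchors, or a round fails to split the group, the minimum distance
#' ratio is lowered by 0.1 and the round retried; below `min_ratio` (or at
#' `max_depth`) the group becomes a forced leaf, so no input is ever lost.
#'
#' @param seqs Character vector of unique, equal-length DNA strings.
#' @param config A [partition_config()] list.
#' @return A list of leaves; each leaf is a list with `members` (integer
#'   indices into `seqs`), `depth`, and `forced` (logical). Leaves partition
#'   `seq_along(seqs)` exactly.
#' @export
recursive_partition <- function(seqs, config = partition_config()) {
  stats <- new.env(parent = emptyenv())
  stats$n_rounds <- 0L
  stats$anchors_per_round <- integer(0)
  leaves <- partition_rec(seqs, seq_along(seqs), config, depth = 0L,
                          ratio = config$packing$min_distance_ratio,
                          stats = stats)
  structure(leaves,
            n_rounds = stats$n_rounds,
            anchors_per_round = stats$anchors_per_round)
}

partition_rec <- function(seqs, idx, config, depth, ratio, stats) {
  n <- length(idx)
  if (n <= config$size_threshold) {
    return(list(list(members = idx, depth = depth, forced = FALSE)))
  }
  if (depth >= config$max_depth || ratio < config$min_ratio) {
    warn(sprintf(
      "group of %d sequences became a forced leaf (depth %d, ratio %.2f)",
      n, depth, ratio))
    return(list(list(members = idx, depth = depth, forced = TRUE)))
  }
  pts <- seqs[idx]
  pk <- config$packing
  pk$min_distance_ratio <- ratio
  anchors <- evolve_packing(pts, pk)
  if (length(anchors) < 2L) {
    return(partition_rec(seqs, idx, config, depth, ratio - 0.1, stats))
  }
  frac <- config$fit_fraction %||% (if (n <= 10000L) 1 else 0.1)
  vec <- batch_distance(pts, anchors)
  lab <- birch_partition(vec, n_clusters = length(anchors),
                         radius = config$radius_threshold,
                         fit_fraction = frac)
  stats$n_rounds <- stats$n_rounds + 1L
  stats$anchors_per_round <- c(stats$anchors_per_round, length(anchors))
  if (length(unique(lab)) < 2L) {
    return(partition_rec(seqs, idx, config, depth, ratio - 0.1, stats))
  }
  parts <- split(idx, lab)
  unlist(
    lapply(parts, function(part) {
      partition_rec(seqs, part, config, depth + 1L,
                    config$packing$min_distance_ratio, stats)
    }),
    recursive = FALSE, use.names = FALSE
  )
}
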