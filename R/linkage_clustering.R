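#' Single-linkage clonal clusters at a normalized Hamming cutoff
#'
#' Clusters equal-length sequences into the connected components of the graph
#' joining every pair at normalized Hamming distance at or below `cutoff`
#' (inclusive) — equivalent to cutting a single-linkage dendrogram at the
#' cutoff. The comparison is performed on integer Hamming distances
#' (`hd <= floor(cutoff * L)`), so results carry no floating-point tie
#' ambiguity.
#'
#' @param members Character vector of equal-length DNA strings.
#' @param cutoff Normalized Hamming distance cutoff in `[0, 1]`; default 0.12.
#' @return Integer vector of cluster labels (1-based, in order of first
#'   appearance), one per input sequence.
#' @examples
#' single_linkage_clusters(c("AAAA", "AAAT", "TTTT"), cutoff = 0.30)
#' @export
single_linkage_clusters <- function(members, cutoff = 0.12) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  n <- length(members)
  if (n == 0L) return(integer(0))
  enc <- encode_sequences(members)
  lab <- components_at_cutoff(enc, cutoff)
  as.integer(factor(lab, levels = unique(lab)))
}

# Connected components over integer Hamming edges hd <= floor(cutoff*L + eps).
# Edges are enumerated in row blocks so memory stays bounded for large forced
# leaves.
components_at_cutoff <- function(enc, cutoff, block = 4000L) {
  n <- nrow(enc)
  max_d <- as.integer(floor(cutoff * ncol(enc) + 1e-9))
  if (n == 1L) return(1L)
  edges <- if (n <= block) {
    cpp_pair_edges(enc, max_d)
  } else {
    starts <- seq(1L, n, by = block)
    do.call(rbind, lapply(starts, function(s) {
      e <- s:min(s + block - 1L, n)
      within <- cpp_pair_edges(enc[e, , drop = FALSE], max_d)
      within <- within + (s - 1L)
      if (s + block - 1L >= n) return(within)
      rest <- (s + block):n
      cross <- cpp_hamming_matrix(enc[e, , drop = FALSE],
                                  enc[rest, , drop = FALSE])
      hit <- which(cross <= max_d, arr.ind = TRUE)
      rbind(within,
            cbind(e[hit[, 1L]], rest[hit[, 2L]]))
    }))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

#' Cluster a repertoire of junction sequences into clonal groups
#'
#' Runs the full anchor-clustering workflow: sequences are stratified by
#' junction length (and optionally by V/J gene usage beforehand), each stratum
#' larger than `size_threshold` is recursively partitioned via anchor-distance
#' vectors ([recursive_partition()]), and every resulting leaf is finished
#' with [single_linkage_clusters()] at the clonal cutoff. Cluster ids are
#' globally unique and never span junction lengths.
#'
#' Each length stratum is processed under its own RNG substream derived from
#' `seed`, so results do not depend on processing order.
#'
#' @param data A data frame with at least `sequence_id` and `junction`
#'   columns (validated via [as_repertoire()]), or a repertoire tibble from
#'   [read_repertoire()].
#' @param min_distance_ratio Minimum anchor-pair Hamming distance as a
#'   fraction of junction length (default 0.6).
#' @param population_size,random_material_rate,generations Evolutionary
#'   point-packing controls, see [packing_params()].
#' @param radius_threshold Merge radius of the partitioner (default 0.5).
#' @param size_threshold Maximum leaf size for all-pairs comparison
#'   (default 1000).
#' @param fit_fraction Fraction of rows used to fit the partitioning model
#'   (`NULL` = automatic, see [partition_config()]).
#' @param cutoff Normalized Hamming distance cutoff for single linkage
#'   (default 0.12).
#' @param vj_mode `"none"` (default), `"pre"` (group by shared V/J usage
#'   before clustering) or `"post"` (split clusters by V/J usage afterwards).
#' @param seed Integer seed controlling all randomness of the run.
#' @param dedup Duplicate definition applied when `data` is not yet a
#'   validated repertoire (see [as_repertoire()]).
#' @return An object of class `anchor_clust`: a list with `assignments`
#'   (tibble: `sequence_id`, `junction`, `junction_length`, `v_call`,
#'   `j_call`, `cluster_id`), `clusters` (tibble of per-cluster size and
#'   length), `params`, `stats` (per-stratum leaf counts, depths, anchor
#'   counts), and `duplicates` carried over from input validation. Use
#'   [tidy()] for the assignment table, [glance()] for a one-row summary.
#' @examples
#' reps <- simulate_repertoire(n_clones = 10, clone_size = 8, seed = 1)
#' fit <- cluster_repertoire(reps, seed = 1)
#' glance(fit)
#' @export
cluster_repertoire <- function(data,
                               min_distance_ratio = 0.6,
                               population_size = 1000,
                               random_material_rate = 50,
                               generations = 50,
                               radius_threshold = 0.5,
                               size_threshold = 1000,
                               fit_fraction = NULL,
                               cutoff = 0.12,
                               vj_mode = c("none", "pre", "post"),
                               seed = 1L,
                               dedup = c("vj", "junction", "none")) {
  vj_mode <- match.arg(vj_mode)
  tbl <- as_repertoire(data, dedup = match.arg(dedup))
  params <- list(
    min_distance_ratio = min_distance_ratio,
    population_size = population_size,
    random_material_rate = random_material_rate,
    generations = generations,
    radius_threshold = radius_threshold,
    size_threshold = size_threshold,
    fit_fraction = fit_fraction,
    cutoff = cutoff, vj_mode = vj_mode, seed = as.integer(seed)
  )
  config <- partition_config(
    radius_threshold = radius_threshold,
    size_threshold = size_threshold,
    fit_fraction = fit_fraction,
    packing = packing_params(min_distance_ratio, population_size,
                             random_material_rate, generations)
  )
  if (nrow(tbl) == 0L) {
    return(new_anchor_clust(tbl[0, ], character(0), params, list(), tbl))
  }

  vj_group <- if (vj_mode == "pre") vj_group_keys(tbl) else rep(1L, nrow(tbl))
  strata <- split(seq_len(nrow(tbl)),
                  list(vj_group, tbl$junction_length), drop = TRUE)
  # order-independent: each stratum gets its own seed from (seed, length, vj)
  cluster_ids <- character(nrow(tbl))
  stats <- list()
  for (key in sort(names(strata))) {
    rows <- strata[[key]]
    L <- tbl$junction_length[rows[1L]]
    stratum_seed <- (params$seed %% 100000L) * 20011L +
      (L %% 1000L) * 17L + stratum_hash(key)
    set.seed(stratum_seed %% .Machine$integer.max)
    uq <- unique(tbl$junction[rows])
    leaves <- if (length(uq) <= config$size_threshold) {
      list(list(members = seq_along(uq), depth = 0L, forced = FALSE))
    } else {
      recursive_partition(uq, config)
    }
    lab <- integer(length(uq))
    offset <- 0L
    for (leaf in leaves) {
      cl <- single_linkage_clusters(uq[leaf$members], cutoff)
      lab[leaf$members] <- cl + offset
      offset <- offset + max(cl)
    }
    cluster_ids[rows] <- paste0("g", key, "_", lab[match(tbl$junction[rows], uq)])
    stats[[key]] <- tibble::tibble(
      stratum = key, junction_length = L, n_sequences = length(rows),
      n_unique = length(uq), n_leaves = length(leaves),
      max_depth = max(vapply(leaves, `[[`, integer(1), "depth")),
      n_forced = sum(vapply(leaves, `[[`, logical(1), "forced")),
      n_partition_rounds = attr(leaves, "n_rounds") %||% 0L,
      n_anchors_total = sum(attr(leaves, "anchors_per_round") %||% 0L)
    )
  }
  res <- new_anchor_clust(tbl, cluster_ids, params,
                          dplyr::bind_rows(stats), tbl)
  if (vj_mode == "post") vj_refine_post(res) else res
}

stratum_hash <- function(key) {
  sum(utf8ToInt(key) * seq_len(nchar(key))) %% 9973L
}

new_anchor_clust <- function(tbl, cluster_ids, params, stats, source_tbl) {
  ids <- as.integer(factor(cluster_ids, levels = unique(cluster_ids)))
  assignments <- tibble::tibble(
    sequence_id = tbl$sequence_id,
    junction = tbl$junction,
    junction_length = tbl$junction_length,
    v_call = tbl$v_call,
    j_call = tbl$j_call,
    cluster_id = if (length(ids)) sprintf("AC%06d", ids) else character(0)
  )
  clusters <- assignments |>
    dplyr::count(.data$cluster_id, .data$junction_length, name = "n_members")
  structure(
    list(assignments = assignments,
         clusters = clusters,
         params = params,
         stats = stats,
         duplicates = attr(source_tbl, "duplicates")),
    class = "anchor_clust"
  )
}

#' @export
print.anchor_clust <- function(x, ...) {
  cat("Anchor clustering result\n")
  cat(sprintf("  %d sequences in %d clusters (%d singletons)\n",
              nrow(x$assignments), nrow(x$clusters),
              sum(x$clusters$n_members == 1L)))
  cat(sprintf(
    "  cutoff %.3g, ratio %.2g, radius %.2g, size threshold %d, vj_mode %s\n",
    x$params$cutoff, x$params$min_distance_ratio, x$params$radius_threshold,
    x$params$size_threshold, x$params$vj_mode))
  invisible(x)
}

#' Tidy the per-sequence cluster assignments
#'
#' @param x An `anchor_clust` object.
#' @param ... Unused.
#' @return The assignment tibble (one row per retained sequence).
#' @exportS3Method generics::tidy
tidy.anchor_clust <- function(x, ...) x$assignments

#' One-row summary of a clustering run
#'
#' @param x An `anchor_clust` object.
#' @param ... Unused.
#' @return A one-row tibble with sequence/cluster counts and key parameters.
#' @exportS3Method generics::glance
glance.anchor_clust <- function(x, ...) {
  tibble::tibble(
    n_sequences = nrow(x$assignments),
    n_clusters = nrow(x$clusters),
    n_singletons = sum(x$clusters$n_members == 1L),
    largest_cluster = if (nrow(x$clusters)) max(x$clusters$n_members) else 0L,
    cutoff = x$params$cutoff,
    min_distance_ratio = x$params$min_distance_ratio,
    radius_threshold = x$params$radius_threshold,
    size_threshold = x$params$size_threshold,
    vj_mode = x$params$vj_mode,
    seed = x$params$seed
  )
}

#' Plot the cluster-size distribution of a clustering run
#'
#' @param object An `anchor_clust` object.
#' @param ... Unused.
#' @return A ggplot: log-scaled histogram of cluster sizes.
#' @exportS3Method ggplot2::autoplot
autoplot.anchor_clust <- function(object, ...) {
  ggplot2::ggplot(object$clusters, ggplot2::aes(x = .data$n_members)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cluster size (sequences)", y = "clusters",
                  title = "Clonal cluster size distribution") +
    ggplot2::theme_minimal()
}
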