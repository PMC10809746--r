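#' Group sequences by shared V/J gene usage before clustering
#'
#' Computes the connected components of the graph linking any two sequences
#' that share at least one V gene *and* at least one J gene. Multi-annotated
#' sequences (comma-separated gene calls) chain groups greedily: a sequence
#' annotated `V1,V2` connects sequences annotated `V1` with sequences
#' annotated `V2` (given a shared J). Gene names are compared at gene level
#' (allele suffix after `*` stripped) by default.
#'
#' Sequences with an empty V or J call bypass the grouping and are placed in
#' one shared catch-all group, so datasets without gene annotations (e.g.
#' simulations) still cluster.
#'
#' @param data A repertoire data frame with `v_call` and `j_call` columns
#'   (comma-separated for multiple annotations; empty string for none).
#' @param strip_allele Compare genes with allele designators removed
#'   (default `TRUE`).
#' @param match Which gene sets must overlap: `"both"` (V and J, default),
#'   `"v"`, or `"j"`.
#' @return The input as a tibble with an integer `vj_group` column added;
#'   groups partition the rows.
#' @export
vj_partition_pre <- function(data, strip_allele = TRUE,
                             match = c("both", "v", "j")) {
  tbl <- tibble::as_tibble(data)
  tbl$vj_group <- vj_group_keys(tbl, strip_allele = strip_allele,
                                match = match)
  tbl
}

# Integer group key per row: connected components over shared (V gene, J gene)
# pairs. Two rows are connected iff their V x J gene-pair sets intersect,
# which is exactly "share >= 1 V gene AND >= 1 J gene"; components give the
# greedy transitive expansion. Rows lacking V or J calls share a catch-all.
vj_group_keys <- function(tbl, strip_allele = TRUE,
                          match = c("both", "v", "j")) {
  match <- match.arg(match)
  n <- nrow(tbl)
  if (n == 0L) return(integer(0))
  v <- parse_gene_calls(tbl$v_call, strip_allele)
  j <- parse_gene_calls(tbl$j_call, strip_allele)
  keys <- switch(match,
    both = purrr::map2(v, j, function(vs, js) {
      if (length(vs) == 0L || length(js) == 0L) character(0)
      else as.vector(outer(vs, js, paste, sep = "~"))
    }),
    v = v,
    j = j
  )
  n_keys <- lengths(keys)
  catch_all <- n_keys == 0L
  uk <- unique(unlist(keys, use.names = FALSE))
  memb <- rep(NA_integer_, n)
  if (length(uk) > 0L) {
    # bipartite graph: row vertices 1..n, key vertices n+1..n+|uk|
    rows_rep <- rep.int(seq_len(n), n_keys)
    key_idx <- n + match(unlist(keys, use.names = FALSE), uk)
    g <- igraph::make_empty_graph(n + length(uk), directed = FALSE)
    g <- igraph::add_edges(g, rbind(rows_rep, key_idx))
    memb <- igraph::components(g)$membership[seq_len(n)]
  }
  memb[catch_all] <- if (length(uk)) max(memb, na.rm = TRUE) + 1L else 1L
  as.integer(factor(memb, levels = unique(memb)))
}

#' Refine clusters by V/J gene usage after clustering
#'
#' Splits every distance-based cluster into the connected components of the
#' shared-gene graph (same definition as [vj_partition_pre()]) restricted to
#' its members. Clusters are only ever split or kept, never merged, and the
#' operation is idempotent.
#'
#' @param result An `anchor_clust` object from [cluster_repertoire()].
#' @param strip_allele,match See [vj_partition_pre()].
#' @return An `anchor_clust` object with regenerated cluster ids.
#' @export
vj_refine_post <- function(result, strip_allele = TRUE,
                           match = c("both", "v", "j")) {
  stopifnot(inherits(result, "anchor_clust"))
  match <- match.arg(match)
  asg <- result$assignments
  sub <- unsplit(
    lapply(split(seq_len(nrow(asg)), asg$cluster_id), function(rows) {
      vj_group_keys(asg[rows, , drop = FALSE], strip_allele, match)
    }),
    asg$cluster_id
  )
  new_ids <- paste0(asg$cluster_id, ".", sub)
  out <- result
  ids <- as.integer(factor(new_ids, levels = unique(new_ids)))
  out$assignments$cluster_id <- sprintf("AC%06d", ids)
  out$clusters <- out$assignments |>
    dplyr::count(.data$cluster_id, .data$junction_length, name = "n_members")
  out$params$vj_mode <- "post"
  out
}
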