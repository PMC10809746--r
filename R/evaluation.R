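#' Pairwise confusion counts between a truth and a predicted partition
#'
#' Counts true-positive, false-positive and false-negative *unordered sequence
#' pairs*: a pair is TP when the two sequences are clonally related (same
#' truth id) and co-clustered, FN when related but separated, FP when
#' unrelated but co-clustered. Computed by contingency-table algebra (sums of
#' `choose(n_ij, 2)`), which equals naive enumeration over all `choose(n, 2)`
#' pairs.
#'
#' @param truth Vector of ground-truth clone ids, or a data frame containing
#'   both columns.
#' @param predicted Vector of predicted cluster ids aligned with `truth`;
#'   when `truth` is a data frame, the (tidy-selected) column names.
#' @param truth_col,cluster_col Column names used when `truth` is a data
#'   frame; defaults `"true_clone_id"` and `"cluster_id"`.
#' @return A one-row tibble with integer-valued `tp`, `fp`, `fn` and the
#'   number of sequences `n`.
#' @examples
#' pair_confusion(c("a", "a", "b"), c("x", "x", "x"))  # tp 1, fp 2, fn 0
#' @export
pair_confusion <- function(truth, predicted = NULL,
                           truth_col = "true_clone_id",
                           cluster_col = "cluster_id") {
  if (is.data.frame(truth)) {
    df <- truth
    if (!all(c(truth_col, cluster_col) %in% names(df))) {
      abort(sprintf("columns '%s' and '%s' are required", truth_col, cluster_col))
    }
    truth <- df[[truth_col]]
    predicted <- df[[cluster_col]]
  }
  if (length(truth) != length(predicted)) {
    abort("truth and predicted assignments must cover the same sequences")
  }
  if (anyNA(truth) || anyNA(predicted)) abort("assignments must not contain NA")
  cont <- dplyr::count(tibble::tibble(t = truth, p = predicted), .data$t, .data$p)
  pairs2 <- function(x) sum(choose(x, 2))
  tp <- pairs2(cont$n)
  related <- pairs2(tapply(cont$n, cont$t, sum))
  co_clustered <- pairs2(tapply(cont$n, cont$p, sum))
  tibble::tibble(tp = tp, fp = co_clustered - tp, fn = related - tp,
                 n = length(truth))
}

#' Sensitivity, precision and F-measure from pair confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `precision = TP / (TP + FP)`, and the
#' F-measure is their harmonic mean. Degenerate conventions: sensitivity is 1
#' when no related pairs exist, precision is 1 when nothing is co-clustered,
#' and the F-measure is 0 when sensitivity + precision is 0.
#'
#' @param counts A one-row data frame with `tp`, `fp`, `fn` (from
#'   [pair_confusion()]).
#' @return A one-row tibble with `sensitivity`, `precision`, `f_measure` in
#'   `[0, 1]`.
#' @export
quality_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  sens <- ifelse(tp + fn == 0, 1, tp / (tp + fn))
  prec <- ifelse(tp + fp == 0, 1, tp / (tp + fp))
  fm <- ifelse(sens + prec == 0, 0, 2 * sens * prec / (sens + prec))
  tibble::tibble(sensitivity = sens, precision = prec, f_measure = fm)
}

#' Pairwise clustering quality against ground-truth clones
#'
#' Convenience wrapper: joins a clustering result to ground truth and returns
#' sensitivity, precision and F-measure, either pooled over all pairs
#' (default) or computed per junction-length group and averaged — the two
#' reporting modes used for simulated-repertoire evaluations.
#'
#' @param result An `anchor_clust` object, or a data frame with cluster and
#'   truth columns.
#' @param truth Data frame with `sequence_id` and `true_clone_id` (ignored if
#'   `result` already carries a `true_clone_id` column); typically the
#'   simulator output.
#' @param by `"pooled"` (all pairs together) or `"length"` (per
#'   junction-length metrics, then unweighted mean across lengths).
#' @return A one-row tibble: `sensitivity`, `precision`, `f_measure`.
#' @export
cluster_quality <- function(result, truth = NULL,
                            by = c("pooled", "length")) {
  by <- match.arg(by)
  df <- if (inherits(result, "anchor_clust")) tidy(result) else
    tibble::as_tibble(result)
  if (!"true_clone_id" %in% names(df)) {
    if (is.null(truth)) abort("ground-truth clone ids are required")
    df <- dplyr::inner_join(
      df, dplyr::select(tibble::as_tibble(truth), "sequence_id",
                        "true_clone_id"),
      by = "sequence_id"
    )
  }
  if (by == "pooled") {
    quality_metrics(pair_confusion(df))
  } else {
    df |>
      dplyr::group_by(.data$junction_length) |>
      dplyr::group_modify(~ quality_metrics(pair_confusion(.x))) |>
      dplyr::ungroup() |>
      dplyr::summarise(dplyr::across(
        c("sensitivity", "precision", "f_measure"), mean))
  }
}

#' Singleton and non-singleton purity metrics against categorical labels
#'
#' Evaluates a clustering against sample labels (e.g. disease state) when
#' true clonal relationships are unknown. A cluster is *pure* when all its
#' members carry the same label; singletons count as pure. Reported as
#' percentages:
#' * `singleton_retention` — singletons / total sequences
#' * `singleton_fraction` — singletons / total clusters
#' * `non_singleton_retention` — sequences in pure non-singleton clusters /
#'   total sequences
#' * `non_singleton_fraction` — pure non-singleton clusters / total clusters
#'
#' @param result An `anchor_clust` object or data frame with `cluster_id`.
#' @param labels Data frame with `sequence_id` and `label` (ignored if a
#'   `label` column is already present).
#' @return A one-row tibble with the four percentages and the underlying
#'   counts (`n_singletons`, `n_pure_non_singleton`, `n_clusters`, `n`).
#' @export
purity_metrics <- function(result, labels = NULL) {
  df <- if (inherits(result, "anchor_clust")) tidy(result) else
    tibble::as_tibble(result)
  if (!"label" %in% names(df)) {
    if (is.null(labels)) abort("sequence labels are required")
    df <- dplyr::inner_join(
      df, dplyr::select(tibble::as_tibble(labels), "sequence_id", "label"),
      by = "sequence_id"
    )
  }
  if (anyNA(df$label)) abort("every clustered sequence must be labelled")
  per <- df |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(size = dplyr::n(),
                     pure = dplyr::n_distinct(.data$label) == 1L)
  n <- nrow(df)
  n_clusters <- nrow(per)
  n_singleton <- sum(per$size == 1L)
  pure_ns <- per$size > 1L & per$pure
  tibble::tibble(
    singleton_retention = 100 * n_singleton / n,
    singleton_fraction = 100 * n_singleton / n_clusters,
    non_singleton_retention = 100 * sum(per$size[pure_ns]) / n,
    non_singleton_fraction = 100 * sum(pure_ns) / n_clusters,
    n_singletons = n_singleton,
    n_pure_non_singleton = sum(pure_ns),
    n_clusters = n_clusters,
    n = n
  )
}
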