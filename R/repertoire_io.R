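#' Read a junction-sequence repertoire from AIRR TSV or FASTA
#'
#' Reads an AIRR-style rearrangement table (tab-separated, header row) or a
#' plain FASTA of junction nucleotide sequences, validates the junctions, and
#' collapses exact duplicates. Junctions are uppercased; records whose junction
#' is empty or contains characters outside `A/C/G/T` (e.g. `N`) are dropped and
#' counted, never silently edited.
#'
#' Duplicate collapsing keeps the first record of each duplicate set and
#' remembers the discarded ids so cluster assignments can be re-expanded on
#' output (see [write_clusters()]). By default two records are duplicates when
#' they share the junction *and* the V and J gene-call sets, which keeps
#' V/J-aware workflows lossless; `dedup = "junction"` matches datasets without
#' gene calls (e.g. simulated repertoires), and `dedup = "none"` disables
#' collapsing.
#'
#' @param path Path to the input file.
#' @param format `"airr_tsv"` (default) or `"fasta"`.
#' @param column_map Optional named list overriding the default AIRR column
#'   names, e.g. `list(junction = "cdr3_nt")`. Recognized names:
#'   `sequence_id`, `junction`, `v_call`, `j_call`, `label`, `true_clone_id`.
#' @param dedup Duplicate definition: `"vj"` (junction + gene-call sets,
#'   default), `"junction"`, or `"none"`.
#' @return A tibble of retained records with columns `sequence_id`,
#'   `junction`, `junction_length`, `v_call`, `j_call` (empty strings when
#'   absent) and, when present in the input, `label` and `true_clone_id`.
#'   Attributes record provenance: `duplicates` (tibble with `duplicate_id`,
#'   `retained_id`), `ambiguous_ids`, and `n_input`, so that
#'   `n_input = nrow(retained) + length(ambiguous_ids) + nrow(duplicates)`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "sequence_id\tjunction\tv_call\tj_call",
#'   "s1\tACGTACGT\tIGHV1-2\tIGHJ4",
#'   "s2\tACGTACGT\tIGHV1-2\tIGHJ4",
#'   "s3\tACNTACGT\tIGHV3-7\tIGHJ6"
#' ), tsv)
#' rep <- read_repertoire(tsv)
#' nrow(rep)                      # 1 retained
#' attr(rep, "duplicates")       # s2 collapsed onto s1
#' attr(rep, "ambiguous_ids")    # s3 dropped (contains N)
#' @export
read_repertoire <- function(path, format = c("airr_tsv", "fasta"),
                            column_map = NULL,
                            dedup = c("vj", "junction", "none")) {
  format <- match.arg(format)
  dedup <- match.arg(dedup)
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  if (format == "airr_tsv") {
    cols <- utils::modifyList(
      list(sequence_id = "sequence_id", junction = "junction",
           v_call = "v_call", j_call = "j_call", label = "label",
           true_clone_id = "true_clone_id"),
      as.list(column_map %||% list())
    )
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (nrow(raw) == 0L) abort(sprintf("input file is empty: %s", path))
    if (!cols$junction %in% names(raw)) {
      abort(sprintf("junction column '%s' not found in %s", cols$junction, path))
    }
    df <- tibble::tibble(
      sequence_id = if (cols$sequence_id %in% names(raw))
        raw[[cols$sequence_id]] else paste0("seq", seq_len(nrow(raw))),
      junction = raw[[cols$junction]],
      v_call = if (cols$v_call %in% names(raw)) raw[[cols$v_call]] else "",
      j_call = if (cols$j_call %in% names(raw)) raw[[cols$j_call]] else ""
    )
    if (cols$label %in% names(raw)) df$label <- raw[[cols$label]]
    if (cols$true_clone_id %in% names(raw))
      df$true_clone_id <- raw[[cols$true_clone_id]]
  } else {
    df <- read_fasta_tbl(path)
    if (nrow(df) == 0L) abort(sprintf("input file is empty: %s", path))
  }
  as_repertoire(df, dedup = dedup)
}

# FASTA input via Biostrings; description line = sequence_id. Gene-call
# columns are left empty (FASTA carries no annotations).
read_fasta_tbl <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  tibble::tibble(
    sequence_id = trimws(names(ss)),
    junction = as.character(ss),
    v_call = "", j_call = ""
  )
}

#' Validate an in-memory repertoire table
#'
#' Applies the same validation and duplicate collapsing as [read_repertoire()]
#' to a data frame already in memory (for example the output of
#' [simulate_repertoire()]).
#'
#' @param df Data frame with at least a `junction` column; `sequence_id`,
#'   `v_call`, `j_call`, `label`, `true_clone_id` are used when present.
#' @inheritParams read_repertoire
#' @return A validated repertoire tibble (see [read_repertoire()]).
#' @export
as_repertoire <- function(df, dedup = c("vj", "junction", "none")) {
  dedup <- match.arg(dedup)
  if (inherits(df, "repertoire_tbl")) return(df)
  if (!"junction" %in% names(df)) abort("column 'junction' is required")
  n_input <- nrow(df)
  df <- tibble::as_tibble(df)
  if (!"sequence_id" %in% names(df)) {
    df$sequence_id <- paste0("seq", seq_len(nrow(df)))
  }
  if (anyDuplicated(df$sequence_id)) {
    abort("sequence_id values must be unique")
  }
  for (col in c("v_call", "j_call")) {
    if (!col %in% names(df)) df[[col]] <- ""
    df[[col]][is.na(df[[col]])] <- ""
  }
  df$junction <- toupper(ifelse(is.na(df$junction), "", df$junction))

  keep <- grepl("^[ACGT]+$", df$junction)
  ambiguous_ids <- df$sequence_id[!keep]
  df <- df[keep, , drop = FALSE]

  dup_key <- switch(dedup,
    none = df$sequence_id,
    junction = df$junction,
    vj = paste(df$junction, gene_set_key(df$v_call), gene_set_key(df$j_call),
               sep = "|")
  )
  first_idx <- !duplicated(dup_key)
  rep_id <- df$sequence_id[first_idx][match(dup_key, dup_key[first_idx])]
  duplicates <- tibble::tibble(
    duplicate_id = df$sequence_id[!first_idx],
    retained_id = rep_id[!first_idx]
  )
  out <- df[first_idx, , drop = FALSE]
  out$junction_length <- nchar(out$junction)
  front <- intersect(
    c("sequence_id", "junction", "junction_length", "v_call", "j_call",
      "label", "true_clone_id"),
    names(out)
  )
  out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  structure(out,
    duplicates = duplicates,
    ambiguous_ids = ambiguous_ids,
    n_input = n_input,
    class = c("repertoire_tbl", class(out))
  )
}

# Canonical key for a comma-separated gene-call string as an unordered set.
gene_set_key <- function(calls) {
  if (length(calls) == 0L) return(character(0))
  vapply(strsplit(ifelse(is.na(calls), "", calls), ","), function(g) {
    paste(sort(unique(trimws(g[nzchar(trimws(g))]))), collapse = ",")
  }, character(1))
}

# Parse comma-separated gene calls into a list of gene-name sets, optionally
# stripped to gene level (text before "*").
parse_gene_calls <- function(calls, strip_allele = TRUE) {
  if (length(calls) == 0L) return(list())
  lapply(strsplit(ifelse(is.na(calls), "", calls), ","), function(g) {
    g <- trimws(g[nzchar(trimws(g))])
    if (strip_allele) g <- sub("\\*.*$", "", g)
    unique(g)
  })
}

#' Write cluster assignments to TSV
#'
#' Writes one row per input sequence with columns `sequence_id`, `junction`,
#' `junction_length`, `v_call`, `j_call`, `cluster_id`. Duplicates collapsed on
#' input are re-expanded with the cluster of their retained representative.
#'
#' @param result An `anchor_clust` object from [cluster_repertoire()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(result, path) {
  stopifnot(inherits(result, "anchor_clust"))
  out <- result$assignments[
    , c("sequence_id", "junction", "junction_length", "v_call", "j_call",
        "cluster_id")
  ]
  dups <- result$duplicates
  if (!is.null(dups) && nrow(dups) > 0L) {
    idx <- match(dups$retained_id, out$sequence_id)
    if (anyNA(idx)) abort("duplicate map refers to unassigned sequence ids")
    expanded <- out[idx, , drop = FALSE]
    expanded$sequence_id <- dups$duplicate_id
    out <- dplyr::bind_rows(out, expanded)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
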