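write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("reading drops ambiguous junctions and collapses duplicates", {
  path <- write_tsv_fixture(c(
    "sequence_id\tjunction",
    "id1\tACGT",
    "id2\tACGT",
    "id3\tACNT"
  ))
  rep <- read_repertoire(path)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$sequence_id, "id1")
  expect_equal(attr(rep, "duplicates"),
               tibble::tibble(duplicate_id = "id2", retained_id = "id1"))
  expect_equal(attr(rep, "ambiguous_ids"), "id3")
  # conservation: input rows = retained + ambiguous + duplicates
  expect_equal(attr(rep, "n_input"),
               nrow(rep) + length(attr(rep, "ambiguous_ids")) +
                 nrow(attr(rep, "duplicates")))
})

test_that("multi-valued gene calls are parsed as sets", {
  path <- write_tsv_fixture(c(
    "sequence_id\tjunction\tv_call\tj_call",
    "s1\tACGTAC\tIGHV1-2,IGHV1-3\tIGHJ4"
  ))
  rep <- read_repertoire(path)
  expect_setequal(parse_gene_calls(rep$v_call)[[1]], c("IGHV1-2", "IGHV1-3"))
})

test_that("duplicate definition respects gene-call context", {
  path <- write_tsv_fixture(c(
    "sequence_id\tjunction\tv_call\tj_call",
    "s1\tACGTAC\tIGHV1\tIGHJ4",
    "s2\tACGTAC\tIGHV2\tIGHJ4",
    "s3\tacgtac\tIGHV1\tIGHJ4"
  ))
  by_vj <- read_repertoire(path, dedup = "vj")
  expect_equal(nrow(by_vj), 2)  # s3 collapses onto s1 (case-insensitive)
  expect_equal(attr(by_vj, "duplicates")$duplicate_id, "s3")
  by_junc <- read_repertoire(path, dedup = "junction")
  expect_equal(nrow(by_junc), 1)
})

test_that("FASTA input yields records with empty gene calls", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGA", ">c", "TTTT"), path)
  rep <- read_repertoire(path, format = "fasta")
  expect_equal(nrow(rep), 3)
  expect_equal(rep$sequence_id, c("a", "b", "c"))
  expect_true(all(rep$v_call == "" & rep$j_call == ""))
})

test_that("input errors are specific", {
  path <- write_tsv_fixture(c("sequence_id\tcdr3", "s1\tACGT"))
  expect_error(read_repertoire(path), "junction")
  rep <- read_repertoire(path, column_map = list(junction = "cdr3"))
  expect_equal(rep$junction, "ACGT")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sequence_id\tjunction", empty)
  expect_error(read_repertoire(empty), "empty")
  dup_ids <- write_tsv_fixture(c("sequence_id\tjunction", "s1\tACGT",
                                 "s1\tAGGT"))
  expect_error(read_repertoire(dup_ids), "unique")
})

test_that("write_clusters re-expands duplicates and round-trips", {
  path <- write_tsv_fixture(c(
    "sequence_id\tjunction",
    "id1\tACGTAA",
    "id2\tACGTAA",
    "id3\tTTTTTT"
  ))
  rep <- read_repertoire(path)
  fit <- cluster_repertoire(rep, seed = 3)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_clusters(fit, out)
  written <- readr::read_tsv(out, show_col_types = FALSE)
  expect_setequal(written$sequence_id, c("id1", "id2", "id3"))
  expect_equal(written$cluster_id[written$sequence_id == "id2"],
               written$cluster_id[written$sequence_id == "id1"])
  # round trip: re-reading the written table preserves assignments
  back <- readr::read_tsv(out, show_col_types = FALSE)
  expect_true(same_partition(
    back$cluster_id[match(written$sequence_id, back$sequence_id)],
    written$cluster_id
  ))
})

test_that("clustering an empty result writes a header-only file", {
  sim <- simulate_repertoire(n_clones = 2, clone_size = 2, seed = 5)
  fit <- cluster_repertoire(sim[0, ], seed = 1)
  expect_equal(nrow(fit$assignments), 0)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_clusters(fit, out)
  expect_equal(nrow(readr::read_tsv(out, show_col_types = FALSE)), 0)
})
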