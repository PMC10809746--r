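vj_tbl <- function(v, j, junction = NULL) {
  n <- length(v)
  if (is.null(junction)) junction <- rand_junctions(n, 12)
  tibble::tibble(
    sequence_id = paste0("s", seq_len(n)),
    junction = junction,
    junction_length = nchar(junction),
    v_call = v, j_call = j
  )
}

test_that("pre-clustering groups require a shared V and a shared J", {
  set.seed(441)
  g <- vj_partition_pre(vj_tbl(c("V1", "V2"), c("J1", "J1")))
  expect_equal(dplyr::n_distinct(g$vj_group), 2)
  g <- vj_partition_pre(vj_tbl(c("V1", "V1"), c("J1", "J1")))
  expect_equal(dplyr::n_distinct(g$vj_group), 1)
})

test_that("multi-annotated sequences chain groups greedily", {
  set.seed(442)
  g <- vj_partition_pre(vj_tbl(c("V1", "V1,V2", "V2"), rep("J1", 3)))
  expect_equal(dplyr::n_distinct(g$vj_group), 1)
  # without the bridging middle sequence the ends stay apart
  g2 <- vj_partition_pre(vj_tbl(c("V1", "V2"), rep("J1", 2)))
  expect_equal(dplyr::n_distinct(g2$vj_group), 2)
})

test_that("empty gene calls fall into one catch-all group", {
  set.seed(443)
  g <- vj_partition_pre(vj_tbl(c("", "", "V1"), c("", "J9", "J1")))
  expect_equal(g$vj_group[1], g$vj_group[2])  # both lack a usable V/J pair
  expect_false(g$vj_group[3] == g$vj_group[1])
})

test_that("allele designators are ignored at gene level by default", {
  set.seed(444)
  g <- vj_partition_pre(vj_tbl(c("IGHV1-2*01", "IGHV1-2*04"),
                               c("IGHJ4*02", "IGHJ4*01")))
  expect_equal(dplyr::n_distinct(g$vj_group), 1)
  g2 <- vj_partition_pre(vj_tbl(c("IGHV1-2*01", "IGHV1-2*04"),
                                c("IGHJ4*02", "IGHJ4*01")),
                         strip_allele = FALSE)
  expect_equal(dplyr::n_distinct(g2$vj_group), 2)
})

test_that("post-clustering refinement splits mixed clusters and is idempotent", {
  set.seed(445)
  junction <- rep(strrep("ACG", 4), 4)  # identical junctions, one cluster
  sim <- vj_tbl(c("V1", "V1,V3", "V2", "V2"), c("J1", "J1", "J2", "J2"),
                junction = junction)
  fit <- cluster_repertoire(sim, seed = 1, dedup = "none")
  expect_equal(dplyr::n_distinct(tidy(fit)$cluster_id), 1)
  ref <- vj_refine_post(fit)
  asg <- tidy(ref)
  expect_equal(dplyr::n_distinct(asg$cluster_id), 2)
  expect_equal(asg$cluster_id[1], asg$cluster_id[2])  # shared V1 and J1
  ref2 <- vj_refine_post(ref)
  expect_identical(tidy(ref2)$cluster_id, tidy(ref)$cluster_id)
})

test_that("refinement only ever splits distance clusters, never merges", {
  set.seed(446)
  sim <- simulate_repertoire(n_clones = 15, clone_size = 6,
                             simulate_gene_calls = TRUE, seed = 446)
  fit <- cluster_repertoire(sim, seed = 2, dedup = "none")
  ref <- vj_refine_post(fit)
  joined <- dplyr::inner_join(
    dplyr::select(tidy(fit), sequence_id, before = cluster_id),
    dplyr::select(tidy(ref), sequence_id, after = cluster_id),
    by = "sequence_id"
  )
  # each refined cluster maps into exactly one original cluster
  nesting <- joined |>
    dplyr::distinct(after, before) |>
    dplyr::count(after)
  expect_true(all(nesting$n == 1))
  expect_setequal(joined$sequence_id, tidy(fit)$sequence_id)
})

test_that("vj modes agree on single-annotation data with clean separation", {
  set.seed(447)
  sim <- simulate_repertoire(n_clones = 12, clone_size = 8,
                             junction_lengths = 30L, mutation_rate = 0.01,
                             simulate_gene_calls = TRUE,
                             multi_annotation_prob = 0, seed = 447)
  pre <- cluster_repertoire(sim, vj_mode = "pre", seed = 3)
  post <- cluster_repertoire(sim, vj_mode = "post", seed = 3)
  both <- dplyr::inner_join(
    dplyr::select(tidy(pre), sequence_id, pre = cluster_id),
    dplyr::select(tidy(post), sequence_id, post = cluster_id),
    by = "sequence_id"
  )
  expect_true(same_partition(both$pre, both$post))
})
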