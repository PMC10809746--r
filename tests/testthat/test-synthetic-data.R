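test_that("zero mutation rate collapses each clone to one unique junction", {
  sim <- simulate_repertoire(n_clones = 4, clone_size = 5, mutation_rate = 0,
                             seed = 461)
  expect_equal(nrow(sim), 20)
  per_clone <- tapply(sim$junction, sim$true_clone_id, dplyr::n_distinct)
  expect_true(all(per_clone == 1))
  rep <- as_repertoire(sim, dedup = "junction")
  expect_equal(nrow(rep), 4)
})

test_that("every clone lives on a single junction length from the menu", {
  sim <- simulate_repertoire(n_clones = 30, clone_size = 6, seed = 462)
  lens <- tapply(sim$junction_length, sim$true_clone_id, dplyr::n_distinct)
  expect_true(all(lens == 1))
  expect_true(all(sim$junction_length %in% c(48, 51, 54, 57, 60)))
  expect_true(all(nchar(sim$junction) == sim$junction_length))
})

test_that("a fixed seed reproduces the repertoire byte for byte", {
  s1 <- simulate_repertoire(n_clones = 10, clone_size = 6, seed = 463)
  s2 <- simulate_repertoire(n_clones = 10, clone_size = 6, seed = 463)
  expect_identical(s1, s2)
  s3 <- simulate_repertoire(n_clones = 10, clone_size = 6, seed = 464)
  expect_false(identical(s1$junction, s3$junction))
})

test_that("between-clone distances match the uniform-germline expectation", {
  # unrelated uniform-random germlines mismatch at each site with prob 3/4
  set.seed(465)
  sims <- simulate_repertoire(n_clones = 60, clone_size = 1,
                              junction_lengths = 48L, mutation_rate = 0,
                              seed = 465)
  d <- batch_distance(sims$junction, sims$junction)
  vals <- d[upper.tri(d)]
  se <- sqrt(0.75 * 0.25 / 48) / sqrt(length(vals))
  # pairs share germlines pairwise-independently; allow a generous band
  expect_lt(abs(mean(vals) - 0.75), 20 * se)
})

test_that("within-clone distances sit stochastically below between-clone", {
  sim <- simulate_repertoire(n_clones = 12, clone_size = 10,
                             junction_lengths = 51L, seed = 466)
  d <- batch_distance(sim$junction, sim$junction)
  same <- outer(sim$true_clone_id, sim$true_clone_id, "==")
  ut <- upper.tri(d)
  within <- d[ut & same]
  between <- d[ut & !same]
  expect_lt(max(within), min(between))
  expect_lt(stats::median(within), 0.12)
  # union bound on the expected within-clone distance
  r <- 0.025; depth <- 2
  expect_lt(mean(within), 1 - (1 - r)^(2 * depth) + 0.02)
})

test_that("stochastic clone-size distributions are supported", {
  sizes_geo <- simulate_repertoire(
    n_clones = 50, clone_size = list(dist = "geometric", p = 0.2),
    seed = 467
  ) |> dplyr::count(true_clone_id)
  expect_true(all(sizes_geo$n >= 1))
  expect_gt(dplyr::n_distinct(sizes_geo$n), 3)
  sizes_pl <- simulate_repertoire(
    n_clones = 50, clone_size = list(dist = "powerlaw", alpha = 2.5, max = 50),
    seed = 468
  ) |> dplyr::count(true_clone_id)
  expect_true(all(sizes_pl$n >= 1 & sizes_pl$n <= 50))
  expect_error(simulate_repertoire(n_clones = 2, clone_size = 0), "at least 1")
})

test_that("labelled mixtures keep clones label-pure at equal proportions", {
  mix <- simulate_labelled_mixture(
    list(covid = list(n_clones = 8, clone_size = 5),
         healthy = list(n_clones = 8, clone_size = 5)),
    seed = 469
  )
  expect_equal(nrow(mix), 80)
  expect_equal(as.integer(table(mix$label)), c(40L, 40L))
  purity <- tapply(mix$label, mix$true_clone_id, dplyr::n_distinct)
  expect_true(all(purity == 1))
})

test_that("gene-call simulation annotates clones consistently", {
  sim <- simulate_repertoire(n_clones = 10, clone_size = 6,
                             simulate_gene_calls = TRUE,
                             multi_annotation_prob = 0.5, seed = 470)
  j_per_clone <- tapply(sim$j_call, sim$true_clone_id, dplyr::n_distinct)
  expect_true(all(j_per_clone == 1))
  expect_true(any(grepl(",", sim$v_call)))
  first_v <- vapply(strsplit(sim$v_call, ","), `[`, character(1), 1)
  expect_true(all(tapply(first_v, sim$true_clone_id,
                         dplyr::n_distinct) == 1))
})
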