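null_annot <- function(seqs, comp, n_mut = 2L) {
  tibble::tibble(vdj_seq = seqs, compartment = comp,
                 n_mut = rep_len(n_mut, length(seqs)))
}

test_that("identical compartments give full overlap and p near one", {
  seqs <- c("AAA", "CCC", "GGG", "TTT")
  annot <- null_annot(rep(seqs, 2), rep(c("a", "b"), each = 4))
  res <- overlap_test(annot, n_shuffles = 200, seed = 1)
  expect_equal(res$observed_overlap, 4L)
  expect_gt(res$p_lower, 0.95)
})

test_that("the mutation filter and empty compartments are enforced", {
  annot <- null_annot(c("AAA", "CCC", "AAA", "GGG"),
                      c("a", "a", "b", "b"), n_mut = c(5L, 1L, 5L, 5L))
  res <- overlap_test(annot, n_shuffles = 50, min_mutations = 2, seed = 2)
  expect_equal(res$observed_overlap, 1L)  # the shared AAA clone
  only_a <- null_annot(c("AAA", "CCC"), c("a", "b"), n_mut = c(3L, 1L))
  expect_error(overlap_test(only_a, n_shuffles = 10), "empty")
})

test_that("sampled null matches the exact permutation distribution on toys", {
  set.seed(77)
  seqs <- c("AAA", "AAA", "CCC", "GGG", "CCC", "TTT", "AAA", "GGG")
  comp <- rep(c("a", "b"), each = 4)
  exact <- exact_overlap_null(seqs, 4L)
  res <- overlap_test(null_annot(seqs, comp), n_shuffles = 4000, seed = 8)
  # distribution match within Monte-Carlo error
  for (v in sort(unique(exact))) {
    p_exact <- mean(exact == v)
    p_hat <- mean(res$null_overlaps == v)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(p_hat - p_exact), 4 * se + 1e-9)
  }
  # p_lower converges to the exact lower tail (pseudo-count vanishes)
  p_exact_tail <- mean(exact <= res$observed_overlap)
  expect_lt(abs(res$p_lower - p_exact_tail), 0.03)
})

test_that("disjoint two-by-two toy matches exact enumeration", {
  seqs <- c("AAA", "CCC", "GGG", "TTT")
  comp <- c("a", "a", "b", "b")
  exact <- exact_overlap_null(seqs, 2L)
  res <- overlap_test(null_annot(seqs, comp), n_shuffles = 3000, seed = 5)
  expect_equal(res$observed_overlap, 0L)
  expect_lt(abs(res$p_lower - mean(exact <= 0L)), 0.03)
})

test_that("overlap results are reproducible given a seed", {
  seqs <- replicate(30, rand_dna(9))
  annot <- null_annot(sample(seqs, 60, replace = TRUE),
                      rep(c("a", "b"), 30))
  r1 <- overlap_test(annot, n_shuffles = 100, seed = 99)
  r2 <- overlap_test(annot, n_shuffles = 100, seed = 99)
  expect_identical(r1$null_overlaps, r2$null_overlaps)
  expect_identical(glance(r1), glance(r2))
})

test_that("generated repertoires with no sharing give small p", {
  cfg <- synth_config(n_lineages = 30, shared_fraction = 0,
                      n_rounds_lambda = 4, muts_per_round_lambda = 2,
                      seed = 21)
  syn <- generate_repertoire(cfg)
  annot <- annotate_repertoire(syn$records, cfg$germline)
  # two sequencing instances per clone: the shuffled null can then place
  # copies of one clone into both compartments while the truth cannot
  annot <- annot[rep(seq_len(nrow(annot)), each = 2), ]
  res <- overlap_test(annot, n_shuffles = 500, seed = 3)
  expect_equal(res$observed_overlap, 0L)
  expect_lt(res$p_lower, 0.05)
})

test_that("the randomized null p-value is uniform and the reported p valid", {
  set.seed(99)
  pool <- replicate(60, rand_dna(30))
  stats <- replicate(200, {
    seqs <- sample(pool, 120, replace = TRUE, prob = 1 / seq_len(60))
    annot <- null_annot(seqs, sample(rep(c("a", "b"), 60)))
    ov <- overlap_test(annot, n_shuffles = 199)
    ties <- sum(ov$null_overlaps == ov$observed_overlap)
    below <- sum(ov$null_overlaps < ov$observed_overlap)
    c(p = ov$p_lower,
      p_rand = (below + stats::runif(1) * (ties + 1)) / 200)
  })
  # the tie-randomized p-value is exactly uniform under exchangeability
  ks <- suppressWarnings(stats::ks.test(stats["p_rand", ], "punif"))
  expect_gt(ks$p.value, 0.01)
  # the reported (+1 pseudo-count) p is valid: never anti-conservative
  grid <- seq(0.05, 1, by = 0.05)
  violation <- max(vapply(grid, function(x) {
    mean(stats["p", ] <= x) - x
  }, numeric(1)))
  expect_lt(violation, 0.08)  # 2 x binomial SE at n = 200
})
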