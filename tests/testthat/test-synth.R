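test_that("generation is deterministic given the seed", {
  cfg <- synth_config(n_lineages = 8, seed = 15)
  s1 <- generate_repertoire(cfg)
  s2 <- generate_repertoire(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
})

test_that("isotype closed loop: planted motifs are recovered exactly", {
  cfg <- synth_config(
    n_lineages = 25, seed = 33,
    isotype_mix = list(ln = c(IgA = 1), lung = c(IgA = 1))
  )
  syn <- generate_repertoire(cfg)
  ann <- classify_isotypes(syn$records)
  expect_true(all(ann$isotype == "IgA"))

  cfg2 <- synth_config(n_lineages = 30, seed = 34)
  syn2 <- generate_repertoire(cfg2)
  ann2 <- classify_isotypes(syn2$records)
  expect_identical(ann2$isotype, syn2$truth$true_isotype)
})

test_that("mutation positions and counts are recovered through annotation", {
  cfg <- synth_config(n_lineages = 25, n_rounds_lambda = 3, seed = 35)
  syn <- generate_repertoire(cfg)
  annot <- annotate_repertoire(syn$records, cfg$germline)
  expect_equal(annot$n_mut, syn$truth$n_true_mutations)
  recovered <- purrr::map2_lgl(
    annot$nt_mutations, syn$truth$true_positions,
    function(m, truth) setequal(m$germline_pos, truth)
  )
  expect_true(all(recovered))
})

test_that("planted shared clones are recovered exactly", {
  cfg <- synth_config(n_lineages = 20, shared_fraction = 0.5,
                      n_rounds_lambda = 4, muts_per_round_lambda = 2,
                      seed = 36)
  syn <- generate_repertoire(cfg)
  annot <- annotate_repertoire(syn$records, cfg$germline)
  clones <- define_clones(annot)
  # sequence-level sharing is the ground truth (planted sharing plus any
  # convergent identical clones arising independently in both compartments)
  truly_shared <- intersect(
    syn$truth$true_vdj_seq[syn$truth$compartment == "ln"],
    syn$truth$true_vdj_seq[syn$truth$compartment == "lung"]
  )
  found_shared <- clones$defining_seq[grepl(",", clones$compartments)]
  expect_setequal(found_shared, truly_shared)
  expect_true(all(syn$truth$true_vdj_seq[syn$truth$shared] %in% truly_shared))
  # with >= 2 mutations per clone, observed overlap = planted shared count
  res <- overlap_test(annot, n_shuffles = 100, seed = 4)
  eligible_shared <- unique(syn$truth$true_vdj_seq[
    syn$truth$shared & syn$truth$n_true_mutations >= 2
  ])
  expect_equal(res$observed_overlap, length(eligible_shared))
})

test_that("key-mutation planting is restricted to the configured compartment", {
  cfg <- synth_config(n_lineages = 40, shared_fraction = 0,
                      key_mutation_prob = c(ln = 1, lung = 0), seed = 37)
  syn <- generate_repertoire(cfg)
  annot <- annotate_repertoire(syn$records, cfg$germline)
  has_w33l <- grepl("W33L", annot$key_mutations)
  expect_true(all(has_w33l[annot$compartment == "ln"]))
  expect_false(any(has_w33l[annot$compartment == "lung"]))
})

test_that("a neutral generator reproduces the enumeration R/S baseline", {
  cfg <- synth_config(n_lineages = 150, shared_fraction = 0,
                      selection_strength = 1, n_rounds_lambda = 4,
                      muts_per_round_lambda = 2,
                      key_mutation_prob = c(ln = 0, lung = 0), seed = 38)
  syn <- generate_repertoire(cfg)
  annot <- annotate_repertoire(syn$records, cfg$germline)
  g <- cfg$germline
  regions <- g$regions$region
  r <- sum(purrr::map_dbl(annot$counts, ~sum(.x$n_r)))
  s <- sum(purrr::map_dbl(annot$counts, ~sum(.x$n_s)))
  baseline <- expected_random_rs(g, regions, stop_handling = "replacement")
  # binomial sampling error of the R/(R+S) proportion, propagated to R/S
  p0 <- baseline / (1 + baseline)
  n <- r + s
  p_hat <- r / n
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(p_hat - p0), 3 * se)
})

test_that("selection raises the observed R/S above the neutral ratio", {
  mk <- function(strength, seed) {
    cfg <- synth_config(n_lineages = 80, shared_fraction = 0,
                        selection_strength = strength,
                        n_rounds_lambda = 4, muts_per_round_lambda = 2,
                        key_mutation_prob = c(ln = 0, lung = 0),
                        seed = seed)
    syn <- generate_repertoire(cfg)
    annot <- annotate_repertoire(syn$records, cfg$germline)
    rs_ratio(annot, regions = cfg$germline$regions$region)
  }
  expect_gt(mk(6, 40), mk(1, 41))
})

test_that("written repertoires round-trip through the standard formats", {
  cfg <- synth_config(n_lineages = 5, seed = 50)
  syn <- generate_repertoire(cfg)
  prefix <- file.path(withr::local_tempdir(), "rep")
  paths <- write_synth_repertoire(syn, prefix)
  expect_true(all(file.exists(paths)))
  back <- read_repertoire(paths[1], paths[2])
  expect_equal(back$nt_seq, syn$records$nt_seq)
  expect_equal(back$umi_count, syn$records$umi_count)
})
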