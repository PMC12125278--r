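profile_of <- function(read, g = default_germline()) {
  call_mutations(align_to_germline(read, g), g)
}

test_that("identity alignments yield empty profiles", {
  g <- default_germline()
  p <- profile_of(g$nt_seq, g)
  expect_equal(sum(p$counts$n_nt), 0)
  expect_equal(nrow(p$aa_mutations), 0L)
  expect_false(p$frame_disrupted)
  expect_identical(p$key_mutations, character(0))
  expect_identical(p$vdj_seq, g$nt_seq)
})

test_that("W33L and the other key mutations are detected at germline numbering", {
  g <- default_germline()
  # codon 33 TGG -> TTG: tryptophan to leucine
  read <- substitute_at(g$nt_seq, 98, "T")
  p <- profile_of(read, g)
  expect_equal(nrow(p$nt_mutations), 1L)
  expect_identical(p$nt_mutations$class, "replacement")
  expect_identical(p$key_mutations, "W33L")
  expect_equal(p$aa_mutations$aa_pos, 33L)
  expect_identical(p$aa_mutations$read_aa, "L")

  # codon 33 TGG -> CGG: tryptophan to arginine, "other" exchange
  p2 <- profile_of(substitute_at(g$nt_seq, 97, "C"), g)
  expect_identical(p2$key_mutations, "W33other")

  # G57D (GGT -> GAT), K59R (AAG -> AGG), Y101F (TAC -> TTC)
  expect_identical(profile_of(substitute_at(g$nt_seq, 170, "A"), g)$key_mutations, "G57D")
  expect_identical(profile_of(substitute_at(g$nt_seq, 176, "G"), g)$key_mutations, "K59R")
  expect_identical(profile_of(substitute_at(g$nt_seq, 302, "T"), g)$key_mutations, "Y101F")
})

test_that("synonymous third-position changes are silent and keep R unchanged", {
  g <- default_germline()
  # FR3 glycine-like silent change: find a codon whose third base can change silently
  read <- substitute_at(g$nt_seq, 204, "G")  # codon 68 GCC -> GCG (Ala, silent)
  p <- profile_of(read, g)
  expect_equal(nrow(p$nt_mutations), 1L)
  expect_identical(p$nt_mutations$class, "silent")
  expect_equal(sum(p$counts$n_r), 0)
  expect_equal(sum(p$counts$n_s), 1)
  expect_identical(p$aa_mutations$class, "silent")
})

test_that("R + S equals the number of point mutations; indels never count", {
  g <- default_germline()
  set.seed(31)
  for (i in 1:20) {
    read <- mutate_dna(g$nt_seq, sample(1:8, 1))
    p <- profile_of(read, g)
    expect_equal(sum(p$counts$n_r) + sum(p$counts$n_s),
                 nrow(p$nt_mutations))
    expect_equal(p$counts$n_nt_norm,
                 p$counts$n_nt / p$counts$length_nt)
  }
  # a 3-nt (in-frame) deletion: no R/S contribution, frame intact
  read <- paste0(substr(g$nt_seq, 1, 120), substr(g$nt_seq, 124, 360))
  p <- profile_of(read, g)
  expect_false(p$frame_disrupted)
  expect_equal(nrow(p$indels), 1L)
  expect_equal(sum(p$counts$n_nt), 0)
  # a 1-nt deletion disrupts the frame and suppresses downstream aa calls
  read2 <- paste0(substr(g$nt_seq, 1, 120), substr(g$nt_seq, 122, 360))
  p2 <- profile_of(read2, g)
  expect_true(p2$frame_disrupted)
})

test_that("N positions in reads are excluded from mutation calling", {
  g <- default_germline()
  read <- substitute_at(g$nt_seq, 10, "N")
  p <- profile_of(read, g)
  expect_equal(sum(p$counts$n_nt), 0)
})

test_that("rs_ratio sums over regions and returns NA with no silent mutations", {
  g <- default_germline()
  reads <- c(
    substitute_at(g$nt_seq, 98, "T"),          # CDR1 replacement (W33L)
    substitute_at(g$nt_seq, 153, "C")           # CDR2 position
  )
  annot <- annotate_repertoire(make_records(reads), g)
  r <- sum(annot$r_cdr)
  s <- sum(annot$s_cdr)
  if (s > 0) {
    expect_equal(rs_ratio(annot), r / s)
  } else {
    expect_true(is.na(rs_ratio(annot)))
  }
  # direct arithmetic: R = 6, S = 1 gives 6
  fake <- tibble::tibble(counts = list(tibble::tibble(
    region = c("CDR1", "CDR2"), length_nt = c(15L, 51L),
    n_nt = c(4L, 3L), n_nt_norm = 0, n_r = c(4L, 2L), n_s = c(0L, 1L)
  )))
  expect_equal(rs_ratio(fake), 6)
  none <- tibble::tibble(counts = list(tibble::tibble(
    region = "CDR1", length_nt = 15L, n_nt = 0L, n_nt_norm = 0,
    n_r = 0L, n_s = 0L
  )))
  expect_true(is.na(rs_ratio(none)))
})

test_that("random-mutation baseline equals exhaustive enumeration", {
  g <- default_germline()
  # single tryptophan codon: no silent substitution exists
  w_only <- germline_reference(
    "w", "TGG", tibble::tibble(region = "CDR1", start = 0L, end = 3L)
  )
  expect_true(is.na(expected_random_rs(w_only, "CDR1")))

  # two-codon toy region: equals the independent 18-substitution enumeration
  toy <- germline_reference(
    "toy2", "GGATGG", tibble::tibble(region = "CDR1", start = 0L, end = 6L)
  )
  expect_equal(expected_random_rs(toy, "CDR1"),
               enum_rs_oracle(c("GGA", "TGG")))
  expect_equal(expected_random_rs(toy, "CDR1", stop_handling = "replacement"),
               enum_rs_oracle(c("GGA", "TGG"), "replacement"))

  # full V gene and CDR sets against the oracle
  for (rg in list(c("CDR1", "CDR2"), c("FR1", "CDR1", "FR2", "CDR2", "FR3"))) {
    expect_equal(expected_random_rs(g, rg),
                 enum_rs_oracle(maturr:::germline_codons(g, rg)))
  }
})

test_that("the enumeration baseline is invariant under codon order", {
  set.seed(5)
  codons <- c("GCT", "TAC", "AAG", "TGG", "CTC", "GGA")
  seqs <- replicate(5, paste(sample(codons), collapse = ""))
  vals <- vapply(seqs, function(s) {
    g <- germline_reference(
      "perm", s, tibble::tibble(region = "CDR1", start = 0L,
                                end = nchar(s))
    )
    expected_random_rs(g, "CDR1")
  }, numeric(1))
  expect_equal(diff(range(vals)), 0)
})

test_that("substitution logos are UMI-weighted per-position frequencies", {
  g <- default_germline()
  w33l <- substitute_at(g$nt_seq, 98, "T")
  w33r <- substitute_at(g$nt_seq, 97, "C")

  annot1 <- annotate_repertoire(make_records(w33l), g)
  logo1 <- substitution_logo(annot1, g)
  expect_equal(nrow(logo1), 1L)
  expect_equal(logo1$freq, 1.0)
  expect_equal(logo1$aa_pos, 33L)
  expect_identical(logo1$read_aa, "L")

  annot2 <- annotate_repertoire(
    make_records(c(w33l, w33r), umi = c(3L, 1L)), g
  )
  logo2 <- substitution_logo(annot2, g)
  expect_equal(logo2$freq[logo2$read_aa == "L"], 0.75)
  expect_equal(logo2$freq[logo2$read_aa == "R"], 0.25)
  m <- logo_matrix(logo2, g)
  expect_equal(m["33", "L"], 0.75)
  expect_equal(sum(m), 1.0)

  # no mutations -> all-zero matrix
  annot0 <- annotate_repertoire(make_records(g$nt_seq), g)
  logo0 <- substitution_logo(annot0, g)
  expect_equal(nrow(logo0), 0L)
  expect_equal(sum(logo_matrix(logo0, g)), 0)
})
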