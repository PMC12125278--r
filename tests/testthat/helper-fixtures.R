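# In-code fixtures shared across test files.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

mutate_dna <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  for (p in sample(length(ch), k)) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# 24-nt two-region toy germline (no stop codons): MAKW | GYKL
toy_germline <- function() {
  germline_reference(
    "toy",
    "ATGGCCAAATGGGGATATAAGCTC",
    tibble::tibble(region = c("FR1", "CDR1"),
                   start = c(0L, 12L), end = c(12L, 24L))
  )
}

# records tibble built directly in code
make_records <- function(seqs, compartment = "ln", population = "GC",
                         umi = 1L, prefix = "r") {
  tibble::tibble(
    read_id = sprintf("%s%03d", prefix, seq_along(seqs)),
    nt_seq = seqs,
    compartment = rep_len(compartment, length(seqs)),
    population = rep_len(population, length(seqs)),
    umi_count = rep_len(as.integer(umi), length(seqs)),
    isotype = "unclassified"
  )
}
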