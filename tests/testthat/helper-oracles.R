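# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive results from first principles (plain-R
# dynamic programming, exhaustive enumeration) and never call the code
# paths they validate.

# Optimal global alignment score with affine gaps (Gotoh three-state DP);
# a gap of length L costs gap_open + L * gap_extend.
nw_score_oracle <- function(a, b, sc = alignment_scoring()) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (A aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- sc$gap_open + i * sc$gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- sc$gap_open + j * sc$gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (A[i] == B[j]) sc$match else sc$mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1, j + 1] <- max(
        M[i, j + 1] + sc$gap_open + sc$gap_extend,
        X[i, j + 1] + sc$gap_extend,
        Y[i, j + 1] + sc$gap_open + sc$gap_extend
      )
      Y[i + 1, j + 1] <- max(
        M[i + 1, j] + sc$gap_open + sc$gap_extend,
        Y[i + 1, j] + sc$gap_extend,
        X[i + 1, j] + sc$gap_open + sc$gap_extend
      )
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive single-substitution R/S over a set of codons.
enum_rs_oracle <- function(codons, stop_handling = "exclude") {
  bases <- c("A", "C", "G", "T")
  r <- s <- 0L
  for (cd in codons) {
    aa0 <- unname(Biostrings::GENETIC_CODE[cd])
    for (i in 1:3) {
      for (b in setdiff(bases, substr(cd, i, i))) {
        cd2 <- cd
        substr(cd2, i, i) <- b
        aa1 <- unname(Biostrings::GENETIC_CODE[cd2])
        if (aa1 == aa0) {
          s <- s + 1L
        } else if (aa1 == "*") {
          if (stop_handling == "replacement") r <- r + 1L
        } else {
          r <- r + 1L
        }
      }
    }
  }
  if (s == 0L) NA_real_ else r / s
}

# Greedy grow-from-root cost for one fixed attachment order, inserting
# substitution intermediates left to right (equal-length sequences only).
greedy_order_cost <- function(root, order_seqs) {
  apply_subs_ltr <- function(from, to) {
    f <- strsplit(from, "")[[1]]
    tt <- strsplit(to, "")[[1]]
    out <- character(0)
    for (i in which(f != tt)) {
      f[i] <- tt[i]
      out <- c(out, paste(f, collapse = ""))
    }
    out
  }
  nodes <- root
  cost <- 0L
  for (s in order_seqs) {
    d <- utils::adist(s, nodes)
    j <- which.min(d)
    cost <- cost + min(d)
    nodes <- unique(c(nodes, apply_subs_ltr(nodes[j], s)))
  }
  cost
}

# Minimum greedy cost over every attachment order (brute force).
steiner_order_oracle <- function(root, seqs) {
  best <- Inf
  rec <- function(cur, rest) {
    if (!length(rest)) {
      best <<- min(best, greedy_order_cost(root, seqs[cur]))
      return()
    }
    for (k in seq_along(rest)) rec(c(cur, rest[k]), rest[-k])
  }
  rec(integer(0), seq_along(seqs))
  best
}

# Exact permutation distribution of the two-compartment overlap for a
# small instance: enumerate every assignment of n_a instances to the
# first compartment.
exact_overlap_null <- function(seqs, n_a) {
  n <- length(seqs)
  combs <- utils::combn(n, n_a)
  apply(combs, 2, function(idx) {
    length(intersect(unique(seqs[idx]), unique(seqs[-idx])))
  })
}
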