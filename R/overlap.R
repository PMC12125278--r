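#' Shuffle-based compartment-overlap test
#'
#' Tests whether the number of clonal sequences observed in both of two
#' compartments is lower than expected if sequences were randomly mixed
#' between them. The observed overlap is the number of distinct FR1-FR4
#' sequences (with at least `min_mutations` nucleotide mutations)
#' present in both compartments. The null distribution is built by
#' pooling all sequence instances (one per record) and reassigning
#' compartment labels at random, preserving each compartment's instance
#' count, `n_shuffles` times. The lower-tail p-value uses the +1
#' pseudo-count convention, `p = (#\{null <= observed\} + 1) /
#' (n_shuffles + 1)`, so it is never exactly zero.
#'
#' @param annot Annotation tibble from [annotate_repertoire()] with
#'   exactly two compartments (or `compartments` naming which two to
#'   use).
#' @param n_shuffles Number of random reassignments (default 1000).
#' @param min_mutations Minimum nucleotide mutation count for a sequence
#'   to enter the analysis (default 2, i.e. more than one mutation).
#' @param seed Optional integer seed for the shuffles.
#' @param compartments Optional character vector of two compartment
#'   labels.
#' @return An object of class `overlap_result`: list with
#'   `observed_overlap`, `expected_overlap` (null mean), `p_lower`,
#'   `null_overlaps`, `n_shuffles`, `min_mutations`, `seed`, and
#'   `n_instances` (per-compartment instance counts).
#' @export
overlap_test <- function(annot, n_shuffles = 1000, min_mutations = 2,
                         seed = NULL, compartments = NULL) {
  compartments <- compartments %||% sort(unique(annot$compartment))
  annot <- annot[annot$n_mut >= min_mutations, ]
  if (length(compartments) != 2L) {
    stop("overlap_test needs exactly two compartments, got: ",
         paste(compartments, collapse = ", "), call. = FALSE)
  }
  annot <- annot[annot$compartment %in% compartments, ]
  n_inst <- table(factor(annot$compartment, levels = compartments))
  if (any(n_inst == 0L)) {
    stop("compartment empty after the mutation filter: ",
         paste(compartments[n_inst == 0L], collapse = ", "), call. = FALSE)
  }
  seqs <- annot$vdj_seq
  in_a <- annot$compartment == compartments[1]
  observed <- length(intersect(unique(seqs[in_a]), unique(seqs[!in_a])))
  if (!is.null(seed)) set.seed(seed)
  n <- length(seqs)
  n_a <- sum(in_a)
  null_overlaps <- vapply(seq_len(n_shuffles), function(i) {
    idx_a <- sample.int(n, n_a)
    length(intersect(unique(seqs[idx_a]), unique(seqs[-idx_a])))
  }, integer(1))
  structure(
    list(
      observed_overlap = observed,
      expected_overlap = mean(null_overlaps),
      p_lower = (sum(null_overlaps <= observed) + 1) / (n_shuffles + 1),
      null_overlaps = null_overlaps,
      n_shuffles = n_shuffles,
      min_mutations = min_mutations,
      seed = seed,
      n_instances = stats::setNames(as.integer(n_inst), compartments)
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> observed %d, expected %.2f (null over %d shuffles), p_lower = %.4g\n",
    x$observed_overlap, x$expected_overlap, x$n_shuffles, x$p_lower
  ))
  invisible(x)
}

#' Tidiers for maturr result objects
#'
#' [generics::tidy()] returns per-element detail (null draws, edges,
#' per-run statistics); [generics::glance()] returns a one-row summary.
#'
#' @param x An `overlap_result`, `lineage_tree`, `sim_result` or
#'   `sim_ensemble`.
#' @param ... Unused.
#' @name tidy-maturr
NULL

#' @rdname tidy-maturr
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble::tibble(shuffle = seq_along(x$null_overlaps),
                 overlap = x$null_overlaps)
}

#' @rdname tidy-maturr
#' @export
glance.overlap_result <- function(x, ...) {
  tibble::tibble(
    observed_overlap = x$observed_overlap,
    expected_overlap = x$expected_overlap,
    p_lower = x$p_lower,
    n_shuffles = x$n_shuffles,
    min_mutations = x$min_mutations
  )
}
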