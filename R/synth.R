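#' Synthetic repertoire configuration
#'
#' Parameters of the ground-truth repertoire generator. Lineages are
#' grown from the germline as chains of point-mutation rounds; each
#' emitted sequence gets an isotype-specific constant-region motif, a
#' UMI count, and a compartment label, and a configurable fraction of
#' lineages is present in both compartments. Defaults emulate a
#' two-compartment (lymph node / lung) response: an IgG1-dominated
#' isotype mix with IgA essentially restricted to the lung, replacement
#' selection above the neutral baseline, and the W33L key mutation
#' planted preferentially in lymph-node lineages.
#'
#' @param germline A [germline_reference()].
#' @param compartments Two compartment labels.
#' @param n_lineages Lineages per compartment (private lineages plus the
#'   shared pool).
#' @param shared_fraction Fraction of each compartment's lineages drawn
#'   from a pool present in both compartments.
#' @param n_rounds_lambda Poisson mean of mutation rounds per lineage
#'   (0 rounds leaves the germline sequence unmutated).
#' @param muts_per_round_lambda Poisson mean (zero-truncated) of point
#'   mutations added per round.
#' @param selection_strength Acceptance multiplier for replacement over
#'   silent proposals; 1 is neutral, values > 1 favour replacement.
#' @param cdr_bias Relative proposal weight per CDR position versus a
#'   framework position (1 = uniform).
#' @param key_mutation_prob Named per-compartment probability that a
#'   lineage has the W33L key mutation planted.
#' @param isotype_mix Named list (per compartment) of isotype proportion
#'   vectors over IgM, IgG1, IgG2a, IgG2b, IgG3, IgA; each must sum
#'   to 1.
#' @param umi_geom_prob Success probability of the geometric UMI-count
#'   distribution (counts are 1 + geometric).
#' @param emit_intermediates If `TRUE`, every mutation round emits a
#'   sequence (deeper lineage trees); otherwise only the final state.
#' @param population Population label for all records.
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(germline = default_germline(),
                         compartments = c("ln", "lung"),
                         n_lineages = 40,
                         shared_fraction = 0.1,
                         n_rounds_lambda = 2,
                         muts_per_round_lambda = 1.5,
                         selection_strength = 3,
                         cdr_bias = 1,
                         key_mutation_prob = c(ln = 0.35, lung = 0.02),
                         isotype_mix = list(
                           ln = c(IgM = 0.10, IgG1 = 0.50, IgG2a = 0.15,
                                  IgG2b = 0.12, IgG3 = 0.08, IgA = 0.05),
                           lung = c(IgM = 0.10, IgG1 = 0.45, IgG2a = 0.15,
                                    IgG2b = 0.10, IgG3 = 0.05, IgA = 0.15)
                         ),
                         umi_geom_prob = 1 / 3,
                         emit_intermediates = FALSE,
                         population = "GC",
                         seed = 42L) {
  stopifnot(
    length(compartments) == 2L, n_lineages >= 1,
    shared_fraction >= 0, shared_fraction <= 1,
    selection_strength > 0, cdr_bias > 0,
    all(names(isotype_mix) %in% compartments),
    umi_geom_prob > 0, umi_geom_prob <= 1
  )
  for (mix in isotype_mix) {
    stopifnot(abs(sum(mix) - 1) < 1e-8)
  }
  structure(
    list(germline = germline, compartments = compartments,
         n_lineages = as.integer(n_lineages),
         shared_fraction = shared_fraction,
         n_rounds_lambda = n_rounds_lambda,
         muts_per_round_lambda = muts_per_round_lambda,
         selection_strength = selection_strength, cdr_bias = cdr_bias,
         key_mutation_prob = key_mutation_prob, isotype_mix = isotype_mix,
         umi_geom_prob = umi_geom_prob,
         emit_intermediates = emit_intermediates,
         population = population, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# constant-region stub (short CH1 context) carrying the classifying motif
isotype_constant_stub <- function(isotype, motifs = isotype_motifs()) {
  base <- switch(
    isotype,
    IgM = motifs$motifs[["IgM"]],
    IgA = motifs$motifs[["IgA"]],
    {
      m <- motifs$motifs[["IgG"]]
      bases <- motifs$igg_subclasses[[isotype]]
      if (is.null(bases)) stop("no subclass rule for ", isotype, call. = FALSE)
      wild <- which(strsplit(m, "")[[1]] == "N")
      for (k in seq_along(wild)) substr(m, wild[k], wild[k]) <- bases[[k]]
      m
    }
  )
  paste0("GCCAAAACGACACCC", base, "TCTGTCTATCCACTG")
}

#' Generate a ground-truth synthetic repertoire
#'
#' Simulates mutation-chain lineages from the germline under configurable
#' replacement selection, plants key mutations, appends isotype motifs
#' and UMI counts, copies a configured fraction of lineages into both
#' compartments, and returns the records together with a truth table for
#' closed-loop validation of the annotation and clonal modules.
#'
#' Proposals are uniform single-nucleotide substitutions over FR1-FR4
#' (optionally CDR-biased); a proposal is accepted with probability 1
#' for silent changes and `selection_strength / max(1,
#' selection_strength)` versus `1 / max(1, selection_strength)` for
#' replacement versus silent, so `selection_strength = 1` reproduces the
#' uniform random-mutation process that the enumeration baseline
#' [expected_random_rs()] describes.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_repertoire`: `records` (repertoire
#'   tibble ready for [annotate_repertoire()]), `truth` (tibble
#'   `read_id`, `lineage_id`, `compartment`, `shared`, `true_isotype`,
#'   `n_true_mutations`, `true_positions` list-column of mutated
#'   germline positions, `true_vdj_seq`, `key_planted`), and the
#'   `config`.
#' @export
generate_repertoire <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  g <- config$germline
  gchars <- strsplit(g$nt_seq, "")[[1]]
  n <- length(gchars)
  region_pos <- region_by_position(g)
  pos_weight <- ifelse(startsWith(region_pos, "CDR"), config$cdr_bias, 1)
  bases <- c("A", "C", "G", "T")
  accept <- c(silent = 1, replacement = 1) *
    c(1, config$selection_strength) / max(1, config$selection_strength)
  names(accept) <- c("silent", "replacement")

  codon_aa <- function(chars, ci) {
    translate_nt(paste(chars[(3 * ci - 2):(3 * ci)], collapse = ""))
  }

  mutate_once <- function(chars) {
    repeat {
      p <- sample.int(n, 1L, prob = pos_weight)
      b <- sample(setdiff(bases, chars[p]), 1L)
      ci <- (p - 1L) %/% 3L + 1L
      old_aa <- codon_aa(chars, ci)
      new <- chars
      new[p] <- b
      cls <- if (codon_aa(new, ci) == old_aa) "silent" else "replacement"
      if (stats::runif(1) <= accept[[cls]]) return(new)
    }
  }

  n_shared <- round(config$shared_fraction * config$n_lineages)
  plan <- dplyr::bind_rows(
    if (n_shared > 0) {
      tibble::tibble(lineage_id = sprintf("S%03d", seq_len(n_shared)),
                     origin = "shared")
    },
    dplyr::bind_rows(lapply(config$compartments, function(cp) {
      k <- config$n_lineages - n_shared
      if (k <= 0) return(NULL)
      tibble::tibble(lineage_id = sprintf("%s%03d", toupper(substr(cp, 1, 1)),
                                          seq_len(k)),
                     origin = cp)
    }))
  )

  records <- list()
  truth <- list()
  for (li in seq_len(nrow(plan))) {
    lineage <- plan$lineage_id[li]
    origin <- plan$origin[li]
    comps <- if (origin == "shared") config$compartments else origin
    # key-mutation planting decided by the lineage's (first) compartment
    key_p <- config$key_mutation_prob[[comps[1]]] %||% 0
    plant <- stats::runif(1) < key_p
    chars <- gchars
    states <- list()
    n_rounds <- stats::rpois(1, config$n_rounds_lambda)
    for (rd in seq_len(n_rounds)) {
      k <- max(1L, stats::rpois(1, config$muts_per_round_lambda))
      for (j in seq_len(k)) chars <- mutate_once(chars)
      if (config$emit_intermediates) states[[length(states) + 1L]] <- chars
    }
    if (plant) {
      # W33L: leucine at amino-acid position 33 (TGG -> TTG)
      if (substr(g$aa_seq, 33, 33) != "W") {
        stop("germline lacks tryptophan 33; cannot plant W33L", call. = FALSE)
      }
      chars[97:99] <- c("T", "T", "G")
    }
    if (!config$emit_intermediates || length(states) == 0L ||
        !identical(states[[length(states)]], chars)) {
      states[[length(states) + 1L]] <- chars
    }
    iso_mix <- config$isotype_mix[[comps[1]]] %||%
      config$isotype_mix[[1]]
    isotype <- sample(names(iso_mix), 1L, prob = iso_mix)
    stub <- isotype_constant_stub(isotype)
    for (cp in comps) {
      for (si in seq_along(states)) {
        st <- states[[si]]
        read_id <- sprintf("%s_%s_%d", cp, lineage, si)
        umi <- 1L + stats::rgeom(1, config$umi_geom_prob)
        vdj <- paste(st, collapse = "")
        mut_pos <- which(st != gchars)
        records[[length(records) + 1L]] <- tibble::tibble(
          read_id = read_id, nt_seq = paste0(vdj, stub),
          compartment = cp, population = config$population,
          umi_count = umi, isotype = "unclassified"
        )
        truth[[length(truth) + 1L]] <- tibble::tibble(
          read_id = read_id, lineage_id = lineage, compartment = cp,
          shared = origin == "shared", true_isotype = isotype,
          n_true_mutations = length(mut_pos),
          true_positions = list(mut_pos),
          true_vdj_seq = vdj,
          key_planted = plant
        )
      }
    }
  }
  structure(
    list(records = dplyr::bind_rows(records),
         truth = dplyr::bind_rows(truth), config = config),
    class = "synth_repertoire"
  )
}

#' @export
print.synth_repertoire <- function(x, ...) {
  cat(sprintf("<synth_repertoire> %d record(s), %d lineage(s), %d UMI(s)\n",
              nrow(x$records), length(unique(x$truth$lineage_id)),
              sum(x$records$umi_count)))
  invisible(x)
}

#' Write a synthetic repertoire to disk
#'
#' Writes the reads FASTA, the metadata TSV and the truth table (JSON)
#' with a common path prefix.
#'
#' @param synth A `synth_repertoire` from [generate_repertoire()].
#' @param out_prefix Output path prefix.
#' @return Invisibly, the three paths.
#' @export
write_synth_repertoire <- function(synth, out_prefix) {
  paths <- paste0(out_prefix, c(".fasta", ".meta.tsv", ".truth.json"))
  write_repertoire(synth$records, paths[1], paths[2])
  truth <- synth$truth
  truth$true_positions <- lapply(truth$true_positions, as.integer)
  jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
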