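#' Annotate a repertoire against the germline
#'
#' The main annotation pipeline: classifies isotypes from constant-region
#' motifs, globally aligns every read to the germline, calls per-region
#' nucleotide and amino-acid mutations with replacement/silent classes,
#' and flags key affinity mutations. One call chains
#' [classify_isotypes()], [align_to_germline()] and [call_mutations()]
#' over the whole table.
#'
#' @param records Repertoire tibble from [read_repertoire()] or
#'   [generate_repertoire()].
#' @param germline A [germline_reference()]; default the packaged
#'   Vh186.2 stand-in.
#' @param scoring An [alignment_scoring()].
#' @param motifs Motif table from [isotype_motifs()].
#' @return `records` augmented with: `score` (alignment score),
#'   `vdj_seq` (read-side FR1-FR4 sequence), `frame_disrupted`,
#'   `n_mut` (total point mutations), `mut_cdr`/`mut_fr` (CDR and
#'   framework totals), `r_cdr`/`s_cdr`, `key_mutations`
#'   (comma-separated), and list-columns `counts`, `nt_mutations`,
#'   `aa_mutations` holding the per-sequence [call_mutations()] tables.
#' @export
annotate_repertoire <- function(records, germline = default_germline(),
                                scoring = alignment_scoring(),
                                motifs = isotype_motifs()) {
  records <- classify_isotypes(records, motifs)
  aligns <- lapply(records$nt_seq, align_to_germline,
                   germline = germline, scoring = scoring)
  profiles <- lapply(aligns, call_mutations, germline = germline)
  cdr <- c("CDR1", "CDR2", "CDR3")
  records$score <- vapply(aligns, `[[`, numeric(1), "score")
  records$vdj_seq <- vapply(profiles, `[[`, character(1), "vdj_seq")
  records$frame_disrupted <- vapply(profiles, `[[`, logical(1),
                                    "frame_disrupted")
  sum_counts <- function(p, col, rg) sum(p$counts[[col]][p$counts$region %in% rg])
  records$n_mut <- vapply(profiles, sum_counts, numeric(1), "n_nt",
                          germline$regions$region)
  records$mut_cdr <- vapply(profiles, sum_counts, numeric(1), "n_nt", cdr)
  records$mut_fr <- records$n_mut - records$mut_cdr
  records$r_cdr <- vapply(profiles, sum_counts, numeric(1), "n_r", cdr)
  records$s_cdr <- vapply(profiles, sum_counts, numeric(1), "n_s", cdr)
  records$key_mutations <- vapply(profiles, function(p) {
    paste(p$key_mutations, collapse = ",")
  }, character(1))
  records$counts <- lapply(profiles, `[[`, "counts")
  records$nt_mutations <- lapply(profiles, `[[`, "nt_mutations")
  records$aa_mutations <- lapply(profiles, `[[`, "aa_mutations")
  records
}

#' Flatten an annotation table for TSV export
#'
#' Drops list-columns and adds per-region mutation counts as ordinary
#' columns so the annotation can round-trip through a TSV file.
#'
#' @param annot Annotation tibble from [annotate_repertoire()].
#' @return A flat tibble with one `mut_<region>` column per region.
#' @export
flatten_annotation <- function(annot) {
  flat <- annot[, !vapply(annot, is.list, logical(1))]
  regions <- annot$counts[[1]]$region
  for (rg in regions) {
    flat[[paste0("mut_", rg)]] <- vapply(annot$counts, function(ci) {
      ci$n_nt[ci$region == rg]
    }, integer(1))
  }
  flat
}

#' Per-group repertoire summary
#'
#' Sequence-level summaries by compartment and population: number of
#' sequences and UMIs, percent of sequences with at least one CDR
#' nucleotide mutation, mean CDR and framework mutation counts, and the
#' CDR R/S ratio.
#'
#' @param annot Annotation tibble from [annotate_repertoire()].
#' @return One row per (compartment, population) group.
#' @export
repertoire_summary <- function(annot) {
  annot |>
    dplyr::group_by(.data$compartment, .data$population) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(
        n_seq = nrow(d),
        n_umi = sum(d$umi_count),
        pct_mutated_cdr = 100 * mean(d$mut_cdr > 0),
        mean_mut_cdr = mean(d$mut_cdr),
        mean_mut_fr = mean(d$mut_fr),
        rs_cdr = ifelse(sum(d$s_cdr) == 0, NA_real_,
                        sum(d$r_cdr) / sum(d$s_cdr))
      )
    }) |>
    dplyr::ungroup()
}
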