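#' Group annotated sequences into clones
#'
#' A clone is the set of sequences sharing an identical FR1-FR4
#' nucleotide sequence (`vdj_seq`). Frame-disrupted sequences are
#' excluded with a message. Clones are ordered by total UMI count
#' (descending), then by sequence, and given stable ids.
#'
#' @param annot Annotation tibble from [annotate_repertoire()].
#' @return A tibble with one row per clone: `clone_id`, `defining_seq`,
#'   `n_members`, `total_umi`, `compartments` (sorted unique labels,
#'   comma-separated), `n_mutations`, `key_mutations`, and `members`
#'   (list-column of read ids).
#' @export
define_clones <- function(annot) {
  dropped <- sum(annot$frame_disrupted)
  if (dropped > 0L) {
    message(dropped, " frame-disrupted sequence(s) excluded from clone definition")
    annot <- annot[!annot$frame_disrupted, ]
  }
  clones <- annot |>
    dplyr::group_by(defining_seq = .data$vdj_seq) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      total_umi = sum(.data$umi_count),
      compartments = paste(sort(unique(.data$compartment)), collapse = ","),
      n_mutations = .data$n_mut[1],
      key_mutations = .data$key_mutations[1],
      members = list(.data$read_id),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$total_umi), .data$defining_seq)
  clones$clone_id <- sprintf("C%04d", seq_len(nrow(clones)))
  dplyr::relocate(clones, "clone_id")
}

#' Clonal-space statistics
#'
#' UMI-weighted clonal space: the fraction occupied by the dominant
#' clone, the mean size of the top clones, and per-clone fractions for
#' pie-style displays.
#'
#' @param clones Clone tibble from [define_clones()].
#' @param top_n Number of top clones to report (default 25).
#' @return A list with `dominant_fraction`, `mean_top_clone_size`, and
#'   `top_fractions` (tibble `clone_id`, `total_umi`, `fraction`,
#'   including a trailing `"other"` row when clones remain).
#' @export
clonal_space <- function(clones, top_n = 25) {
  stopifnot(nrow(clones) >= 1L)
  total <- sum(clones$total_umi)
  ord <- clones[order(-clones$total_umi), ]
  top <- utils::head(ord, top_n)
  top_fractions <- tibble::tibble(
    clone_id = top$clone_id,
    total_umi = top$total_umi,
    fraction = top$total_umi / total
  )
  if (nrow(ord) > top_n) {
    rest <- sum(ord$total_umi[-seq_len(top_n)])
    top_fractions <- dplyr::bind_rows(top_fractions, tibble::tibble(
      clone_id = "other", total_umi = rest, fraction = rest / total
    ))
  }
  list(
    dominant_fraction = ord$total_umi[1] / total,
    mean_top_clone_size = mean(top$total_umi),
    top_fractions = top_fractions
  )
}
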