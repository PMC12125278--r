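#' Call nucleotide and amino-acid mutations from a germline alignment
#'
#' Walks an alignment column-by-column, bins nucleotide mismatches by
#' framework/CDR region, re-translates mutated codons on the read side,
#' and classifies amino-acid changes as replacement or silent. Insertions
#' and deletions are recorded separately and never contribute to R/S
#' counts. A frame-breaking indel (length not a multiple of three) inside
#' FR1-FR4 flags the profile `frame_disrupted` and suppresses amino-acid
#' calls downstream of the indel.
#'
#' Two classifications are reported. Each *nucleotide* mutation is
#' classified by the effect of that substitution alone on its germline
#' codon (the same semantics as the exhaustive-enumeration baseline of
#' [expected_random_rs()]); the per-region `n_r`/`n_s` counts sum these,
#' so R + S always equals the number of point mutations. Each mutated
#' *codon* is additionally classified by comparing its full read-side
#' translation with the germline residue; key mutations (W33L etc.) are
#' detected at this codon level.
#'
#' @param alignment A `bcr_alignment` from [align_to_germline()].
#' @param germline The [germline_reference()] the alignment was made to.
#' @return An object of class `mutation_profile`: list with tibbles
#'   `nt_mutations`, `aa_mutations`, `indels`, `counts` (per region:
#'   `length_nt`, `n_nt`, `n_nt_norm`, `n_r`, `n_s`), a character vector
#'   `key_mutations`, logical `frame_disrupted`, and `vdj_seq` (the
#'   read-side FR1-FR4 sequence used to define clones).
#' @export
call_mutations <- function(alignment, germline) {
  g <- strsplit(alignment$germline_aligned, "")[[1]]
  r <- strsplit(alignment$read_aligned, "")[[1]]
  cmap <- alignment$coordinate_map
  n <- nchar(germline$nt_seq)
  region_of <- region_by_position(germline)

  # read base over each germline position ("-" = deleted, NA = not covered)
  read_at <- rep(NA_character_, n)
  covered <- !is.na(cmap)
  read_at[cmap[covered]] <- r[covered]

  # insertions: runs of germline-gap columns, anchored to the preceding
  # germline position (0 = before the first)
  ins <- tibble::tibble(type = character(), germline_pos = integer(),
                        length = integer())
  gap_cols <- which(!covered)
  if (length(gap_cols)) {
    run_id <- cumsum(c(1L, diff(gap_cols) != 1L))
    for (id in unique(run_id)) {
      cols <- gap_cols[run_id == id]
      prev <- cmap[seq_len(cols[1] - 1L)]
      anchor <- if (any(!is.na(prev))) max(prev, na.rm = TRUE) else 0L
      ins <- dplyr::bind_rows(ins, tibble::tibble(
        type = "insertion", germline_pos = anchor, length = length(cols)
      ))
    }
  }
  del <- tibble::tibble(type = character(), germline_pos = integer(),
                        length = integer())
  del_pos <- which(!is.na(read_at) & read_at == "-")
  if (length(del_pos)) {
    run_id <- cumsum(c(1L, diff(del_pos) != 1L))
    for (id in unique(run_id)) {
      pos <- del_pos[run_id == id]
      del <- dplyr::bind_rows(del, tibble::tibble(
        type = "deletion", germline_pos = pos[1], length = length(pos)
      ))
    }
  }
  indels <- dplyr::bind_rows(ins, del)

  frame_breakers <- indels$germline_pos[indels$length %% 3L != 0L]
  frame_disrupted <- length(frame_breakers) > 0L
  # codons at or after the first frame-breaking indel get no aa calls
  suppress_from_codon <- if (frame_disrupted) {
    (max(1L, min(frame_breakers)) - 1L) %/% 3L + 1L
  } else {
    Inf
  }

  germ_chars <- strsplit(germline$nt_seq, "")[[1]]
  is_point <- !is.na(read_at) & read_at %in% c("A", "C", "G", "T") &
    read_at != germ_chars
  pos <- which(is_point)
  nt_mutations <- tibble::tibble(
    germline_pos = pos,
    region = region_of[pos],
    germline_base = germ_chars[pos],
    read_base = read_at[pos],
    class = vapply(pos, function(p) {
      codon_idx <- (p - 1L) %/% 3L + 1L
      cd <- substr(germline$nt_seq, 3L * codon_idx - 2L, 3L * codon_idx)
      off <- p - (3L * codon_idx - 3L)
      substr(cd, off, off) <- read_at[p]
      if (translate_nt(cd) ==
          substr(germline$aa_seq, codon_idx, codon_idx)) "silent" else "replacement"
    }, character(1))
  )

  # codon-level amino-acid calls for codons carrying >= 1 point mutation
  region_codon <- region_by_codon(germline)
  mut_codons <- sort(unique((pos - 1L) %/% 3L + 1L))
  mut_codons <- mut_codons[mut_codons < suppress_from_codon]
  aa_rows <- lapply(mut_codons, function(ci) {
    bases <- read_at[(3L * ci - 2L):(3L * ci)]
    if (anyNA(bases) || !all(bases %in% c("A", "C", "G", "T"))) return(NULL)
    read_aa <- translate_nt(paste(bases, collapse = ""))
    germ_aa <- substr(germline$aa_seq, ci, ci)
    tibble::tibble(
      aa_pos = ci, region = region_codon[ci],
      germline_aa = germ_aa, read_aa = read_aa,
      class = if (read_aa == germ_aa) "silent" else "replacement"
    )
  })
  aa_mutations <- dplyr::bind_rows(aa_rows)
  if (nrow(aa_mutations) == 0L) {
    aa_mutations <- tibble::tibble(aa_pos = integer(), region = character(),
                                   germline_aa = character(),
                                   read_aa = character(), class = character())
  }

  km <- key_mutation_table()
  keys <- character(0)
  for (i in seq_len(nrow(km))) {
    hit <- aa_mutations$aa_pos == km$aa_pos[i] &
      aa_mutations$germline_aa == km$germline_aa[i] &
      aa_mutations$class == "replacement" &
      (if (is.na(km$read_aa[i])) {
        # "other": any replacement not matching an explicitly named one
        !aa_mutations$read_aa %in%
          km$read_aa[km$aa_pos == km$aa_pos[i] & !is.na(km$read_aa)]
      } else {
        aa_mutations$read_aa == km$read_aa[i]
      })
    if (any(hit)) keys <- c(keys, km$key[i])
  }

  counts <- germline$regions |>
    dplyr::mutate(length_nt = .data$end - .data$start) |>
    dplyr::select("region", "length_nt")
  tally <- function(cls) {
    vapply(counts$region, function(rg) {
      sum(nt_mutations$region == rg & nt_mutations$class %in% cls)
    }, integer(1))
  }
  counts$n_nt <- tally(c("silent", "replacement"))
  counts$n_nt_norm <- counts$n_nt / counts$length_nt
  counts$n_r <- tally("replacement")
  counts$n_s <- tally("silent")

  # read-side FR1-FR4 sequence (insertions inside the span retained)
  span <- which(covered)
  vdj_seq <- if (length(span)) {
    cols <- seq(min(span), max(span))
    paste(r[cols][r[cols] != "-"], collapse = "")
  } else {
    ""
  }

  structure(
    list(nt_mutations = nt_mutations, aa_mutations = aa_mutations,
         indels = indels, counts = counts, key_mutations = keys,
         frame_disrupted = frame_disrupted, vdj_seq = vdj_seq),
    class = "mutation_profile"
  )
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf(
    "<mutation_profile> %d point mutation(s) (%d R / %d S), %d indel(s)%s\n",
    nrow(x$nt_mutations), sum(x$counts$n_r), sum(x$counts$n_s),
    nrow(x$indels),
    if (x$frame_disrupted) ", FRAME DISRUPTED" else ""
  ))
  if (length(x$key_mutations)) {
    cat("  key mutations:", paste(x$key_mutations, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Replacement/silent mutation ratio
#'
#' Sums replacement and silent point mutations over a set of regions
#' across an annotated repertoire and returns their ratio. With zero
#' silent mutations the ratio is undefined and `NA_real_` is returned
#' (never infinity).
#'
#' @param annot Annotation tibble from [annotate_repertoire()] (or a list
#'   of `mutation_profile` objects).
#' @param regions Regions to sum over; default all three CDRs.
#' @param umi_weighted If `TRUE`, each sequence's counts are weighted by
#'   its UMI count.
#' @return A single number, or `NA_real_` when no silent mutations exist.
#' @export
rs_ratio <- function(annot, regions = c("CDR1", "CDR2", "CDR3"),
                     umi_weighted = FALSE) {
  counts <- if (inherits(annot, "tbl_df")) {
    annot$counts
  } else {
    lapply(annot, `[[`, "counts")
  }
  w <- if (umi_weighted && inherits(annot, "tbl_df") &&
           "umi_count" %in% names(annot)) {
    annot$umi_count
  } else {
    rep(1, length(counts))
  }
  r <- s <- 0
  for (i in seq_along(counts)) {
    ci <- counts[[i]]
    sel <- ci$region %in% regions
    r <- r + w[i] * sum(ci$n_r[sel])
    s <- s + w[i] * sum(ci$n_s[sel])
  }
  if (s == 0) NA_real_ else r / s
}

#' Enumerate all single-nucleotide substitutions of a germline region set
#'
#' The exhaustive enumeration behind the random-mutation R/S baseline:
#' every position of every codon in the selected regions is substituted
#' by each of the three alternative bases (equal weight) and the
#' resulting codon is classified as `replacement`, `silent`, or `stop`.
#'
#' @param germline A [germline_reference()].
#' @param regions Character vector of region names.
#' @return A tibble with one row per substitution: `germline_pos`,
#'   `region`, `aa_pos`, `germline_base`, `alt_base`, `germline_aa`,
#'   `alt_aa`, `class`.
#' @export
enumerate_substitutions <- function(germline,
                                    regions = c("FR1", "CDR1", "FR2",
                                                "CDR2", "FR3")) {
  region_codon <- region_by_codon(germline)
  codon_idx <- which(region_codon %in% regions)
  codons <- substring(germline$nt_seq, 3L * codon_idx - 2L, 3L * codon_idx)
  # the three alternatives to each base, in fixed A<C<G<T order
  alt_of <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  out <- vector("list", 9L)
  k <- 0L
  for (off in 1:3) {
    b0 <- substring(codons, off, off)
    for (j in 1:3) {
      alt <- vapply(alt_of[b0], `[[`, character(1), j)
      cd2 <- codons
      substring(cd2, off, off) <- alt
      aa1 <- unname(Biostrings::GENETIC_CODE[cd2])
      aa0 <- substring(germline$aa_seq, codon_idx, codon_idx)
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        germline_pos = 3L * codon_idx - 3L + off,
        region = region_codon[codon_idx],
        aa_pos = codon_idx,
        germline_base = b0, alt_base = alt,
        germline_aa = aa0, alt_aa = aa1,
        class = ifelse(aa1 == "*", "stop",
                       ifelse(aa1 == aa0, "silent", "replacement"))
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$germline_pos, .data$alt_base)
}

#' Random-mutation R/S baseline by exhaustive enumeration
#'
#' The expected replacement/silent ratio of uniformly random single
#' nucleotide substitutions over a germline region set, with no
#' selection: the no-selection reference value against which observed
#' repertoire R/S ratios are compared. Computed exactly by
#' [enumerate_substitutions()] over all 3L substitutions.
#'
#' Substitutions that create a stop codon are excluded by default:
#' productive, expressed receptors (the only ones observed in a
#' repertoire) can carry neither class of nonsense change, so terminator
#' substitutions belong in neither R nor S. Set
#' `stop_handling = "replacement"` to count them as replacement instead.
#'
#' @inheritParams enumerate_substitutions
#' @param stop_handling `"exclude"` (default) or `"replacement"`.
#' @return The R/S ratio; `NA_real_` when the region set admits no
#'   silent substitution (e.g. a single tryptophan codon).
#' @export
expected_random_rs <- function(germline,
                               regions = c("FR1", "CDR1", "FR2",
                                           "CDR2", "FR3"),
                               stop_handling = c("exclude", "replacement")) {
  stop_handling <- match.arg(stop_handling)
  subs <- enumerate_substitutions(germline, regions)
  r <- sum(subs$class == "replacement") +
    if (stop_handling == "replacement") sum(subs$class == "stop") else 0L
  s <- sum(subs$class == "silent")
  if (s == 0L) NA_real_ else r / s
}

#' UMI-weighted amino-acid substitution profile
#'
#' For each amino-acid position in the selected regions, the
#' UMI-weighted frequency with which each non-germline residue is
#' observed across an annotated repertoire: the data behind a sequence
#' logo of selected substitutions. Frequencies at a position sum to that
#' position's total mutated fraction (at most 1).
#'
#' @param annot Annotation tibble from [annotate_repertoire()].
#' @param germline The [germline_reference()] used for annotation.
#' @param regions Regions to profile; default all three CDRs.
#' @param umi_weighted Weight sequences by UMI count (default `TRUE`).
#' @return A tibble `aa_pos`, `region`, `germline_aa`, `read_aa`, `freq`
#'   with one row per observed (position, residue) substitution;
#'   positions with no substitutions are absent (frequency zero). The
#'   total weight is attached as attribute `total_weight`.
#' @export
substitution_logo <- function(annot, germline,
                              regions = c("CDR1", "CDR2", "CDR3"),
                              umi_weighted = TRUE) {
  stopifnot(nrow(annot) >= 1L)
  w <- if (umi_weighted) annot$umi_count else rep(1, nrow(annot))
  total <- sum(w)
  rows <- purrr::map2(annot$aa_mutations, w, function(aa, wi) {
    aa <- aa[aa$class == "replacement" & aa$region %in% regions, ]
    if (nrow(aa) == 0L) return(NULL)
    aa$weight <- wi
    aa
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0L) {
    out <- tibble::tibble(aa_pos = integer(), region = character(),
                          germline_aa = character(), read_aa = character(),
                          freq = numeric())
  } else {
    out <- rows |>
      dplyr::group_by(.data$aa_pos, .data$region, .data$germline_aa,
                      .data$read_aa) |>
      dplyr::summarise(freq = sum(.data$weight) / total, .groups = "drop") |>
      dplyr::arrange(.data$aa_pos, .data$read_aa)
  }
  attr(out, "total_weight") <- total
  out
}

#' Widen a substitution profile into a position-by-residue matrix
#'
#' @param logo Output of [substitution_logo()].
#' @param germline The [germline_reference()].
#' @param regions Regions defining the row set (all positions, including
#'   unmutated ones, appear as rows).
#' @return A numeric matrix, rows named by amino-acid position, columns
#'   by the 20 residues.
#' @export
logo_matrix <- function(logo, germline,
                        regions = c("CDR1", "CDR2", "CDR3")) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pos <- which(region_by_codon(germline) %in% regions)
  m <- matrix(0, nrow = length(pos), ncol = length(aa),
              dimnames = list(pos, aa))
  keep <- logo$aa_pos %in% pos & logo$read_aa %in% aa
  if (any(keep)) {
    m[cbind(match(logo$aa_pos[keep], pos), match(logo$read_aa[keep], aa))] <-
      logo$freq[keep]
  }
  m
}
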