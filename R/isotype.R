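#' Default isotype motif table
#'
#' Constant-region motifs immediately downstream of the V(D)J segment
#' used to classify heavy-chain reads: one motif each for IgM and IgA and
#' a degenerate IgG motif whose three wildcard positions (N1, N2, N3)
#' carry the subclass information. One mismatch is tolerated per motif;
#' wildcard positions never count as mismatches.
#'
#' @param path Optional YAML file overriding the packaged motif table.
#' @return A list with elements `max_mismatches`, `motifs` (named
#'   character vector, `N` = wildcard) and `igg_subclasses` (named list
#'   of length-3 base vectors for N1, N2, N3).
#' @export
isotype_motifs <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "isotype_motifs.yaml", package = "maturr")
  cfg <- yaml::read_yaml(path)
  cfg$motifs <- vapply(cfg$motifs, toupper, character(1))
  cfg
}

# mismatch count of `motif` against every window of `chars`
# (character vector of one read); wildcard offsets and read Ns are free.
motif_mismatches <- function(chars, motif) {
  m <- strsplit(motif, "")[[1]]
  L <- length(m)
  n_win <- length(chars) - L + 1L
  if (n_win < 1L) return(integer(0))
  mm <- integer(n_win)
  win <- seq_len(n_win)
  for (j in seq_len(L)) {
    if (m[j] == "N") next
    cj <- chars[win + j - 1L]
    mm <- mm + (cj != m[j] & cj != "N")
  }
  mm
}

classify_one <- function(nt_seq, motifs) {
  chars <- strsplit(nt_seq, "")[[1]]
  best <- tibble::tibble(isotype = character(), position = integer(),
                         mismatches = integer())
  for (iso in names(motifs$motifs)) {
    mm <- motif_mismatches(chars, motifs$motifs[[iso]])
    ok <- which(mm <= motifs$max_mismatches)
    if (length(ok)) {
      hit <- ok[which.min(mm[ok])]  # leftmost among equal handled by which.min
      best <- dplyr::bind_rows(best, tibble::tibble(
        isotype = iso, position = hit, mismatches = mm[hit]
      ))
    }
  }
  if (nrow(best) == 0L) {
    return(list(isotype = "unclassified", position = NA_integer_,
                mismatches = NA_integer_, subclass_bases = NA_character_))
  }
  lo <- min(best$mismatches)
  best <- best[best$mismatches == lo, ]
  if (nrow(best) > 1L) {
    warning("ambiguous isotype motif hit (tie at ", lo,
            " mismatch(es)); record left unclassified", call. = FALSE)
    return(list(isotype = "unclassified", position = NA_integer_,
                mismatches = NA_integer_, subclass_bases = NA_character_))
  }
  iso <- best$isotype
  pos <- best$position
  subclass_bases <- NA_character_
  if (iso == "IgG") {
    m <- strsplit(motifs$motifs[["IgG"]], "")[[1]]
    wild <- which(m == "N")
    bases <- chars[pos + wild - 1L]
    subclass_bases <- paste(bases, collapse = "")
    iso <- "IgG-unsubtyped"
    for (sub in names(motifs$igg_subclasses)) {
      if (identical(bases, toupper(unlist(motifs$igg_subclasses[[sub]])))) {
        iso <- sub
        break
      }
    }
  }
  list(isotype = iso, position = pos, mismatches = best$mismatches,
       subclass_bases = subclass_bases)
}

#' Classify isotypes from constant-region motifs
#'
#' Scans every read for each motif at every offset (Hamming distance, no
#' indels), tolerating one mismatch outside wildcard positions. An IgG
#' hit is refined to IgG1/IgG2a/IgG2b/IgG3 from the bases at the N1/N2/N3
#' wildcard offsets; unknown combinations give `"IgG-unsubtyped"`. A tie
#' between two different motifs at equal mismatch count leaves the read
#' `"unclassified"` with a warning.
#'
#' @param records Repertoire tibble from [read_repertoire()].
#' @param motifs Motif table from [isotype_motifs()].
#' @return `records` with `isotype` filled in plus columns
#'   `motif_position` (1-based window start), `motif_mismatches` and
#'   `igg_bases` (the observed N1N2N3 bases, IgG only).
#' @export
classify_isotypes <- function(records, motifs = isotype_motifs()) {
  calls <- lapply(records$nt_seq, classify_one, motifs = motifs)
  records$isotype <- vapply(calls, `[[`, character(1), "isotype")
  records$motif_position <- vapply(calls, `[[`, integer(1), "position")
  records$motif_mismatches <- vapply(calls, `[[`, integer(1), "mismatches")
  records$igg_bases <- vapply(calls, `[[`, character(1), "subclass_bases")
  records
}
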