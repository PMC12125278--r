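#' Read a heavy-chain repertoire from FASTA plus a metadata table
#'
#' Each FASTA record is one observed heavy-chain sequence (typically one
#' UMI-collapsed read or one unique clone). Sample annotations come from
#' a tab-separated metadata file mapping `read_id` to `compartment`,
#' `population` and `umi_count`; records missing from the metadata get
#' `umi_count = 1` and `NA` labels.
#'
#' @param fasta_path Path to the reads FASTA.
#' @param metadata_path Optional path to a TSV with columns `read_id`
#'   and any of `compartment`, `population`, `umi_count`.
#' @return A tibble with one row per record: `read_id`, `nt_seq`
#'   (uppercased), `compartment`, `population`, `umi_count`, `isotype`
#'   (initially `"unclassified"`).
#' @export
read_repertoire <- function(fasta_path, metadata_path = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate read_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  nt <- toupper(as.character(seqs))
  bad <- !grepl("^[ACGTN]+$", nt)
  if (any(bad)) {
    stop("non-DNA characters (other than N) in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  records <- tibble::tibble(
    read_id = ids, nt_seq = unname(nt),
    compartment = NA_character_, population = NA_character_,
    umi_count = 1L, isotype = "unclassified"
  )
  if (!is.null(metadata_path)) {
    meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
    stopifnot("read_id" %in% names(meta))
    if (anyDuplicated(meta$read_id)) {
      stop("duplicate read_id in metadata", call. = FALSE)
    }
    idx <- match(records$read_id, meta$read_id)
    for (col in intersect(c("compartment", "population"), names(meta))) {
      records[[col]] <- as.character(meta[[col]])[idx]
    }
    if ("umi_count" %in% names(meta)) {
      umi <- as.integer(meta$umi_count)[idx]
      records$umi_count <- dplyr::coalesce(umi, 1L)
      if (any(records$umi_count < 1L)) {
        stop("umi_count must be >= 1", call. = FALSE)
      }
    }
  }
  records
}

#' Write a repertoire to FASTA plus a metadata TSV
#'
#' Inverse of [read_repertoire()]; used by the synthetic generator and
#' the command-line interface.
#'
#' @param records Repertoire tibble (`read_id`, `nt_seq`, `compartment`,
#'   `population`, `umi_count`).
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, `records`.
#' @export
write_repertoire <- function(records, fasta_path, metadata_path) {
  writeLines(
    paste0(">", records$read_id, "\n", records$nt_seq),
    fasta_path
  )
  readr::write_tsv(
    records[, intersect(c("read_id", "compartment", "population", "umi_count"),
                        names(records))],
    metadata_path
  )
  invisible(records)
}
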