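#' Construct a germline reference
#'
#' A germline reference couples a nucleotide sequence with an ordered
#' framework/CDR region map. All downstream mutation calling, R/S
#' classification and clone definition are expressed in the coordinate
#' system of this reference.
#'
#' @param name Identifier for the germline gene.
#' @param nt_seq Germline nucleotide sequence (A/C/G/T, case-insensitive).
#' @param regions A data frame with columns `region`, `start`, `end`
#'   (0-based half-open nucleotide coordinates). Regions must be
#'   non-overlapping, contiguous, in order FR1, CDR1, FR2, CDR2, FR3,
#'   CDR3, FR4 (a trailing subset is allowed for toy references), cover
#'   the whole sequence, and each span a whole number of codons.
#' @param frame Reading-frame offset of codon 1 (0, 1 or 2).
#' @param check_key_sites If `TRUE`, assert that the translation carries
#'   the residues needed for key-mutation detection (W33, G57, K59, Y101).
#'
#' @return An object of class `germline_reference`: a list with elements
#'   `name`, `nt_seq`, `aa_seq`, `frame` and `regions` (a tibble).
#' @export
germline_reference <- function(name, nt_seq, regions, frame = 0L,
                               check_key_sites = FALSE) {
  nt_seq <- toupper(nt_seq)
  if (!grepl("^[ACGT]+$", nt_seq)) {
    stop("germline sequence must contain only A/C/G/T", call. = FALSE)
  }
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("region", "start", "end") %in% names(regions)))
  canonical <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
  if (!all(regions$region %in% canonical)) {
    stop("unknown region name(s): ",
         paste(setdiff(regions$region, canonical), collapse = ", "),
         call. = FALSE)
  }
  regions <- regions[order(regions$start), ]
  if (is.unsorted(match(regions$region, canonical), strictly = TRUE)) {
    stop("regions must appear in FR1..FR4 order", call. = FALSE)
  }
  n <- nchar(nt_seq)
  if (regions$start[1] != 0L || regions$end[nrow(regions)] != n ||
      any(regions$start[-1] != regions$end[-nrow(regions)])) {
    stop("regions must be contiguous and cover [0, ", n, ")", call. = FALSE)
  }
  if (any((regions$end - regions$start) %% 3L != 0L)) {
    stop("each region must span a whole number of codons", call. = FALSE)
  }
  aa_seq <- translate_nt(substr(nt_seq, frame + 1L, n))
  ref <- structure(
    list(name = name, nt_seq = nt_seq, aa_seq = aa_seq,
         frame = as.integer(frame), regions = regions),
    class = "germline_reference"
  )
  if (check_key_sites) {
    km <- key_mutation_table()
    for (i in seq_len(nrow(km))) {
      pos <- km$aa_pos[i]
      have <- substr(aa_seq, pos, pos)
      if (!nzchar(have) || have != km$germline_aa[i]) {
        stop(sprintf("germline lacks %s at amino-acid position %d (found '%s')",
                     km$germline_aa[i], pos, have), call. = FALSE)
      }
    }
  }
  ref
}

#' @export
print.germline_reference <- function(x, ...) {
  cat(sprintf("<germline_reference> %s: %d nt, %d aa, %d regions\n",
              x$name, nchar(x$nt_seq), nchar(x$aa_seq), nrow(x$regions)))
  print(x$regions)
  invisible(x)
}

#' Read a germline reference from FASTA plus a region-map file
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param regions_path Path to a YAML region map with fields `name`,
#'   `frame` and `regions` (list of `region`/`start`/`end`).
#' @inheritParams germline_reference
#' @return A [germline_reference()] object.
#' @export
read_germline <- function(fasta_path, regions_path, check_key_sites = FALSE) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("germline FASTA must contain exactly one record", call. = FALSE)
  }
  cfg <- yaml::read_yaml(regions_path)
  regions <- dplyr::bind_rows(lapply(cfg$regions, tibble::as_tibble))
  germline_reference(
    name = cfg$name %||% sub("\\s.*$", "", names(seqs)[1]),
    nt_seq = as.character(seqs[[1]]),
    regions = regions,
    frame = cfg$frame %||% 0L,
    check_key_sites = check_key_sites
  )
}

#' Packaged Vh186.2 germline stand-in
#'
#' Returns the reconstructed Vh186.2/IGHV1-72 heavy-chain germline shipped
#' with the package: the canonical V-region protein sequence (tryptophan
#' 33, glycine 57, lysine 59) with a canonical NP-response junction
#' (tyrosine 101 in CDR3) and framework 4. The nucleotide sequence is a
#' synthetic reconstruction, not the IMGT reference allele, and is
#' labelled as such in its FASTA header; sequence-derived constants such
#' as the random-mutation R/S baseline are therefore approximations of
#' the values obtained on the canonical allele.
#'
#' @return A [germline_reference()] object with a full FR1-FR4 region map.
#' @export
default_germline <- function() {
  read_germline(
    system.file("extdata", "vh186_2_synthetic.fasta", package = "maturr"),
    system.file("extdata", "vh186_2_regions.yaml", package = "maturr"),
    check_key_sites = TRUE
  )
}

#' Translate a nucleotide sequence
#'
#' Thin wrapper around [Biostrings::translate()] that tolerates sequences
#' whose length is not a multiple of three (trailing bases are dropped)
#' and returns a plain character string. Stop codons are `*`.
#'
#' @param nt_seq Nucleotide string.
#' @return Amino-acid string.
#' @export
translate_nt <- function(nt_seq) {
  nt_seq <- toupper(nt_seq)
  usable <- 3L * (nchar(nt_seq) %/% 3L)
  if (usable == 0L) return("")
  codons <- substring(nt_seq, seq(1L, usable, 3L), seq(3L, usable, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # codons containing N or gaps
  paste(aa, collapse = "")
}

# region name for each 1-based germline nucleotide position
region_by_position <- function(germline) {
  out <- character(nchar(germline$nt_seq))
  for (i in seq_len(nrow(germline$regions))) {
    out[(germline$regions$start[i] + 1L):germline$regions$end[i]] <-
      germline$regions$region[i]
  }
  out
}

# region name for each 1-based codon index
region_by_codon <- function(germline) {
  region_by_position(germline)[seq(1L, nchar(germline$nt_seq), by = 3L)]
}

# germline codons as a character vector, optionally restricted to regions
germline_codons <- function(germline, regions = NULL) {
  s <- germline$nt_seq
  starts <- seq(1L, nchar(s) - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  if (!is.null(regions)) {
    codons <- codons[region_by_codon(germline) %in% regions]
  }
  codons
}

#' Canonical key-mutation definitions
#'
#' The affinity-relevant heavy-chain exchanges tracked by the annotation
#' pipeline, in germline amino-acid numbering (1-based, sequential over
#' the reference translation): W33L (and W33 to any other residue), G57D,
#' K59R and Y101F.
#'
#' @return A tibble with columns `key`, `aa_pos`, `germline_aa`,
#'   `read_aa` (`NA` means "any residue other than germline").
#' @export
key_mutation_table <- function() {
  tibble::tibble(
    key = c("W33L", "W33other", "G57D", "K59R", "Y101F"),
    aa_pos = c(33L, 33L, 57L, 59L, 101L),
    germline_aa = c("W", "W", "G", "K", "Y"),
    read_aa = c("L", NA, "D", "R", "F")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
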