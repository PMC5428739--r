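# Peptide location, flanking residues and tryptic-status classification.
#
# Status vocabulary used throughout outputs:
#   "tryptic"      both termini consistent with trypsin cleavage
#   "semi-tryptic" exactly one terminus consistent (a neopeptide candidate)
#   "non-tryptic"  neither terminus consistent
#   "not-found"    no exact occurrence in the database

status_levels <- c("tryptic", "semi-tryptic", "non-tryptic", "not-found")

# All occurrences of `peptides` (unique-ified internally) in the proteome.
# Single pass over the concatenated proteome via stringi fixed search with
# overlap, so cost scales with total sequence length, not n_peptides x
# n_proteins. Peptides are letter-only so matches never span the "-" joins.
locate_peptides <- function(peptides, proteins) {
  u <- unique(peptides)
  seqs <- proteins$sequence
  big <- paste(seqs, collapse = "-")
  p_start <- c(0L, cumsum(nchar(seqs) + 1L))[seq_along(seqs)] + 1L

  hits <- stringi::stri_locate_all_fixed(big, u, overlap = TRUE)
  nhit <- vapply(hits, function(m) sum(!is.na(m[, 1L])), integer(1))
  starts_abs <- unlist(lapply(hits, function(m) m[!is.na(m[, 1L]), 1L]),
                       use.names = FALSE)
  if (length(starts_abs) == 0L) {
    return(tibble::tibble(
      peptide = character(), protein_row = integer(),
      start = integer(), end = integer(),
      preceding = character(), following = character(),
      protein_length = integer()
    ))
  }
  pep <- rep(u, nhit)
  idx <- findInterval(starts_abs, p_start)
  start <- as.integer(starts_abs - p_start[idx] + 1L)
  end <- start + nchar(pep) - 1L
  len <- nchar(seqs)[idx]
  tibble::tibble(
    peptide = pep,
    protein_row = idx,
    start = start,
    end = end,
    preceding = ifelse(start == 1L, "-",
                       stringr::str_sub(seqs[idx], start - 1L, start - 1L)),
    following = ifelse(end == len, "-",
                       stringr::str_sub(seqs[idx], end + 1L, end + 1L)),
    protein_length = len
  ) |>
    dplyr::arrange(.data$peptide, .data$protein_row, .data$start)
}

#' Find all occurrences of a peptide in a protein database
#'
#' Exact, possibly overlapping matches in every protein, with the residues
#' immediately preceding and following each occurrence (`"-"` at a protein
#' terminus). Order is deterministic: database order, then start position.
#'
#' @param peptide A single uppercase peptide sequence.
#' @param proteins Protein table from [read_fasta()].
#' @return A tibble with one row per occurrence: `peptide`, `accession`,
#'   `header_token`, `start`, `end`, `preceding`, `following`,
#'   `protein_length`. Empty (zero rows) when the peptide is absent.
#' @export
find_occurrences <- function(peptide, proteins) {
  stopifnot(length(peptide) == 1L, nzchar(peptide))
  locate_peptides(peptide, proteins) |>
    dplyr::mutate(accession = proteins$bare_accession[.data$protein_row],
                  header_token = proteins$header_token[.data$protein_row]) |>
    dplyr::select("peptide", "accession", "header_token", "start", "end",
                  "preceding", "following", "protein_length")
}

#' Classify the tryptic status of peptide locations
#'
#' Sets per-terminus tryptic flags and an overall status for each location.
#' The N-terminus is tryptic when the peptide starts the protein
#' (`start == 1`), starts at position 2 behind an initiator methionine
#' (N-terminal Met excision is ubiquitous in vivo, so it is not evidence of
#' native cleavage), or follows K/R. The C-terminus is tryptic when the
#' peptide ends the protein or its last residue is K/R. With
#' `proline_rule = TRUE` a K/R boundary followed by proline does not count.
#'
#' @param locations A tibble of locations from [find_occurrences()] (or the
#'   internal vectorized scanner); needs columns `peptide`, `start`, `end`,
#'   `preceding`, `following`, `protein_length`.
#' @inheritParams cleavage_sites
#' @return `locations` with logical columns `n_term_tryptic`,
#'   `c_term_tryptic` and a `status` column (`"tryptic"`, `"semi-tryptic"`
#'   or `"non-tryptic"`).
#' @export
classify_locations <- function(locations, proline_rule = FALSE) {
  first <- first_residue(locations$peptide)
  last <- last_residue(locations$peptide)
  kr_nterm <- locations$preceding %in% c("K", "R") &
    (!proline_rule | first != "P")
  kr_cterm <- last %in% c("K", "R") &
    (!proline_rule | locations$following != "P")
  n_ok <- locations$start == 1L |
    (locations$start == 2L & locations$preceding == "M") |
    kr_nterm
  c_ok <- locations$end == locations$protein_length | kr_cterm
  locations$n_term_tryptic <- n_ok
  locations$c_term_tryptic <- c_ok
  locations$status <- dplyr::case_when(
    n_ok & c_ok ~ "tryptic",
    n_ok | c_ok ~ "semi-tryptic",
    .default = "non-tryptic"
  )
  locations
}

#' Resolve a peptide's location among multiple candidate proteins
#'
#' A peptide sequence may occur in several proteins (or several places in
#' one). When it could be either fully tryptic or semi-tryptic, the fully
#' tryptic location is taken as the most likely source; among equal-status
#' locations the first in database order wins (deterministic tie-break).
#'
#' @param locations Classified locations for ONE peptide
#'   ([classify_locations()] output); may have zero rows.
#' @return A one-row tibble: `status` (`"not-found"` when no occurrence),
#'   `n_occurrences`, and the chosen location's columns (NA when not found).
#' @export
resolve_assignment <- function(locations) {
  if (nrow(locations) == 0L) {
    return(tibble::tibble(
      status = "not-found", n_occurrences = 0L,
      accession = NA_character_, header_token = NA_character_,
      start = NA_integer_, end = NA_integer_,
      preceding = NA_character_, following = NA_character_
    ))
  }
  rank <- match(locations$status, status_levels)
  best <- locations[order(rank, locations$protein_row %||% seq_len(nrow(locations)),
                          locations$start), , drop = FALSE][1L, ]
  tibble::tibble(
    status = best$status, n_occurrences = nrow(locations),
    accession = best$accession %||% NA_character_,
    header_token = best$header_token %||% NA_character_,
    start = best$start, end = best$end,
    preceding = best$preceding, following = best$following
  )
}

#' Annotate a vector of measured peptides against a proteome
#'
#' The workhorse "slow path": every peptide is located in the full proteome,
#' each occurrence classified, and multi-protein ambiguity resolved
#' (fully-tryptic location preferred, then first in database order).
#'
#' @param peptides Character vector of peptide sequences (one per
#'   measurement row; duplicates fine).
#' @param proteins Protein table from [read_fasta()].
#' @inheritParams cleavage_sites
#' @return A tibble aligned with `peptides`: `peptide`, `status`,
#'   `accession`, `header_token`, `start`, `end`, `preceding`, `following`,
#'   `n_occurrences`.
#' @examples
#' prot <- tibble::tibble(header_token = "P1", bare_accession = "P1",
#'                        description = "", sequence = "MACDKEFGRHILK")
#' annotate_peptides(c("EFGR", "HIL", "ACDK"), prot)
#' @export
annotate_peptides <- function(peptides, proteins, proline_rule = FALSE) {
  stopifnot(is.character(peptides))
  locs <- locate_peptides(peptides, proteins)
  locs <- classify_locations(locs, proline_rule)
  locs$accession <- proteins$bare_accession[locs$protein_row]
  locs$header_token <- proteins$header_token[locs$protein_row]

  resolved <- locs |>
    dplyr::group_by(.data$peptide) |>
    dplyr::arrange(match(.data$status, status_levels), .data$protein_row,
                   .data$start, .by_group = TRUE) |>
    dplyr::summarise(
      status = dplyr::first(.data$status),
      n_occurrences = dplyr::n(),
      accession = dplyr::first(.data$accession),
      header_token = dplyr::first(.data$header_token),
      start = dplyr::first(.data$start),
      end = dplyr::first(.data$end),
      preceding = dplyr::first(.data$preceding),
      following = dplyr::first(.data$following),
      .groups = "drop"
    )

  out <- tibble::tibble(peptide = peptides) |>
    dplyr::left_join(resolved, by = "peptide")
  missing <- is.na(out$status)
  out$status[missing] <- "not-found"
  out$n_occurrences[missing] <- 0L
  out
}
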