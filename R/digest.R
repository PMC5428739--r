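#' Tryptic cleavage sites of a protein sequence
#'
#' Trypsin cleaves C-terminal to lysine (K) or arginine (R). Returns the
#' 1-based positions after which cleavage occurs; the final residue is never
#' a cleavage site. With `proline_rule = TRUE`, K/R followed by proline is
#' not cleaved (Keil rule, for Mascot-style compatibility); the default is
#' plain K/R specificity.
#'
#' @param sequence Protein sequence (uppercase letters).
#' @param proline_rule Suppress cleavage before proline?
#' @return Sorted integer vector of cleavage positions (possibly empty).
#' @examples
#' cleavage_sites("AKCRD")        # 2, 4
#' cleavage_sites("AKPR", proline_rule = TRUE)
#' @export
cleavage_sites <- function(sequence, proline_rule = FALSE) {
  chars <- stringr::str_split_1(sequence, "")
  n <- length(chars)
  pos <- which(chars == "K" | chars == "R")
  pos <- pos[pos < n]
  if (proline_rule && length(pos)) pos <- pos[chars[pos + 1L] != "P"]
  pos
}

#' In-silico tryptic digestion of one protein
#'
#' Enumerates all fully-tryptic peptides of a protein sequence: the maximal
#' fragments between consecutive cleavage sites (zero missed cleavages) plus
#' every concatenation of up to `max_missed + 1` adjacent fragments.
#'
#' @inheritParams cleavage_sites
#' @param max_missed Maximum number of missed cleavages (internal K/R sites)
#'   allowed within a peptide.
#' @return A tibble with columns `sequence`, `start`, `end` (1-based
#'   inclusive coordinates in the parent) and `missed_cleavages`, ordered by
#'   missed-cleavage count then position.
#' @examples
#' digest_protein("AKCRD", max_missed = 1)
#' @export
digest_protein <- function(sequence, max_missed = 0L, proline_rule = FALSE) {
  stopifnot(max_missed >= 0)
  b <- c(0L, cleavage_sites(sequence, proline_rule), nchar(sequence))
  k <- length(b) - 1L # number of zero-missed fragments
  pieces <- purrr::map(0:min(max_missed, k - 1L), function(m) {
    i <- seq_len(k - m)
    tibble::tibble(start = b[i] + 1L, end = b[i + m + 1L],
                   missed_cleavages = m)
  })
  out <- dplyr::bind_rows(pieces)
  out$sequence <- stringr::str_sub(sequence, out$start, out$end)
  out[c("sequence", "start", "end", "missed_cleavages")]
}

#' Digest every protein of a proteome
#'
#' @param proteins Protein table from [read_fasta()].
#' @inheritParams digest_protein
#' @return A tibble like [digest_protein()]'s with additional leading columns
#'   `accession` (bare accession) and `header_token`.
#' @export
digest_proteome <- function(proteins, max_missed = 0L, proline_rule = FALSE) {
  purrr::map2(proteins$sequence, seq_len(nrow(proteins)), function(s, i) {
    d <- digest_protein(s, max_missed, proline_rule)
    d$accession <- proteins$bare_accession[i]
    d$header_token <- proteins$header_token[i]
    d
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("accession", "header_token", "sequence", "start", "end",
                  "missed_cleavages")
}

#' Build the fully-tryptic peptide dictionary
#'
#' Hash-backed membership structure over every tryptic peptide (up to
#' `max_missed` missed cleavages) of a proteome. Membership queries cost
#' O(1) in proteome size, which is what makes the fast classification path
#' practical for large exports.
#'
#' For proteins starting with methionine the digest products of the
#' des-Met form are indexed too, so that peptides created by N-terminal
#' methionine excision (start position 2 behind Met) are recognised as
#' fully tryptic, exactly as the slow-scan edge rule treats them.
#'
#' @inheritParams digest_proteome
#' @return An object of class `tryptic_index`.
#' @seealso [fast_is_fully_tryptic()]
#' @export
build_tryptic_index <- function(proteins, max_missed = 0L,
                                proline_rule = FALSE) {
  stopifnot(nrow(proteins) > 0L)
  env <- new.env(hash = TRUE, parent = emptyenv())
  met <- startsWith(proteins$sequence, "M") & nchar(proteins$sequence) > 1L
  if (any(met)) {
    clipped <- proteins[met, ]
    clipped$sequence <- stringr::str_sub(clipped$sequence, 2L)
    proteins <- dplyr::bind_rows(proteins, clipped)
  }
  peps <- unique(digest_proteome(proteins, max_missed, proline_rule)$sequence)
  for (s in peps) assign(s, TRUE, envir = env)
  structure(
    list(peptides = env, max_missed = as.integer(max_missed),
         proline_rule = proline_rule, n_proteins = nrow(proteins),
         n_peptides = length(peps)),
    class = "tryptic_index"
  )
}

#' @export
print.tryptic_index <- function(x, ...) {
  cat("<tryptic_index> ", x$n_peptides, " peptides from ", x$n_proteins,
      " proteins (max ", x$max_missed, " missed cleavages",
      if (x$proline_rule) ", proline rule" else "", ")\n", sep = "")
  invisible(x)
}

#' Fast fully-tryptic membership test
#'
#' Dictionary lookup: `TRUE` exactly when the peptide is a tryptic digest
#' product (within the index's missed-cleavage bound) of some protein in the
#' indexed database. This path cannot supply flanking residues -- a
#' dictionary of every possible semi-tryptic peptide is not feasible -- so
#' semi-tryptic candidates always go through the full proteome scan.
#'
#' @param peptides Character vector of peptide sequences.
#' @param index A [build_tryptic_index()] object whose `max_missed` is at
#'   least the peptides' internal cleavage count (see
#'   [infer_missed_cleavages()]).
#' @return Logical vector, one element per peptide.
#' @export
fast_is_fully_tryptic <- function(peptides, index) {
  stopifnot(inherits(index, "tryptic_index"))
  vapply(peptides, exists, logical(1),
         envir = index$peptides, inherits = FALSE, USE.NAMES = FALSE)
}

#' Infer the missed-cleavage setting from observed peptides
#'
#' The dictionary must cover at least as many missed cleavages as the search
#' engine allowed; that number is recovered from the data as the maximum
#' count of internal K/R cleavage sites over all input peptides.
#'
#' @param peptides Non-empty character vector of peptide sequences.
#' @inheritParams cleavage_sites
#' @return A single non-negative integer.
#' @examples
#' infer_missed_cleavages(c("ACK", "ACKDR", "AKRK")) # 2
#' @export
infer_missed_cleavages <- function(peptides, proline_rule = FALSE) {
  if (length(peptides) == 0L) {
    stop("cannot infer missed cleavages from an empty peptide list",
         call. = FALSE)
  }
  max(vapply(peptides,
             function(p) length(cleavage_sites(p, proline_rule)),
             integer(1)))
}
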