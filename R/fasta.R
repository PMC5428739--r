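#' Read a protein database in FASTA format
#'
#' Parses a plain or UniProt-style FASTA file into a protein table. Sequence
#' lines are concatenated, uppercased, and stripped of internal whitespace;
#' a single terminal stop codon (`*`) is removed. The first
#' whitespace-delimited token of each header is kept verbatim, and a bare
#' accession is derived from `db|ACC|NAME`-style tokens so that downstream
#' matching accepts either form.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record, in file order, and columns
#'   `header_token`, `bare_accession`, `description` and `sequence`.
#'
#' Records whose `header_token` duplicates an earlier one are dropped with a
#' warning (the first occurrence wins), so behaviour on malformed databases
#' is deterministic. Any non-letter character remaining in a sequence after
#' normalization is a format error. Non-standard residue codes (B, J, O, U,
#' X, Z) are accepted as ordinary letters.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P12345|TEST_HUMAN Test protein", "ACDE", "FGHK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0L) {
    stop("no FASTA records found in ", path, call. = FALSE)
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("malformed FASTA (sequence data before first header) in ", path,
         call. = FALSE)
  }
  rec <- cumsum(is_hdr)
  headers <- stringr::str_trim(sub("^>", "", lines[is_hdr]))
  n <- length(headers)

  seqs <- rep("", n)
  body <- !is_hdr
  if (any(body)) {
    joined <- vapply(split(lines[body], rec[body]), paste0, character(1),
                     collapse = "")
    seqs[as.integer(names(joined))] <- joined
  }
  seqs <- toupper(stringi::stri_replace_all_regex(seqs, "\\s+", ""))
  seqs <- sub("\\*$", "", seqs)

  bad <- !stringr::str_detect(seqs, "^[A-Z]+$")
  if (any(bad)) {
    stop("malformed FASTA: record '", headers[which(bad)[1L]],
         "' has an empty sequence or non-letter characters", call. = FALSE)
  }

  token <- stringr::str_split_i(headers, "\\s+", 1L)
  desc <- stringr::str_trim(stringr::str_remove(headers, "^\\S+\\s*"))

  dup <- duplicated(token)
  if (any(dup)) {
    warning("duplicate FASTA accession(s) dropped (first kept): ",
            paste(unique(token[dup]), collapse = ", "), call. = FALSE)
  }

  tibble::tibble(
    header_token = token,
    bare_accession = bare_accession(token),
    description = desc,
    sequence = seqs
  )[!dup, ]
}

#' Write a protein table to a FASTA file
#'
#' @param proteins A tibble as returned by [read_fasta()] (columns
#'   `header_token`, `description`, `sequence`).
#' @param path Output path.
#' @param width Sequence line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  hdr <- ifelse(nzchar(proteins$description),
                paste(proteins$header_token, proteins$description),
                proteins$header_token)
  wrap <- function(s) {
    starts <- seq(1L, nchar(s), by = width)
    stringr::str_sub(s, starts, pmin(starts + width - 1L, nchar(s)))
  }
  out <- unlist(purrr::map2(hdr, proteins$sequence,
                            function(h, s) c(paste0(">", h), wrap(s))))
  readr::write_lines(out, path)
  invisible(path)
}
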