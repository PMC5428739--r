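# shared fixture builders (all fixtures are generated in code)

`%||%` <- function(x, y) if (is.null(x)) y else x

protein_tbl <- function(sequences, tokens = NULL) {
  tokens <- tokens %||% sprintf("P%d", seq_along(sequences))
  tibble::tibble(
    header_token = tokens,
    bare_accession = neopeptider:::bare_accession(tokens),
    description = "",
    sequence = sequences
  )
}

write_tmp_fasta <- function(proteins) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  write_fasta(proteins, path)
  path
}

# minimal hand-built Progenesis-style CSV with the documented 3-header-row
# layout; abund is a numeric matrix (rows follow `seqs`)
write_tmp_progenesis <- function(seqs, abund, conditions = c("A", "B"),
                                 accessions = NULL, use_in_quant = NULL,
                                 delim = ",", extra_raw = FALSE) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  n <- length(seqs)
  ns <- ncol(abund)
  half <- ns / 2
  accessions <- accessions %||% rep("", n)
  meta_names <- c("Sequence", "Accession")
  cond_row <- c(conditions[1], rep("", half - 1),
                conditions[2], rep("", half - 1))
  r1 <- c(rep("", 2), "Normalized abundance", rep("", ns - 1))
  r2 <- c(rep("", 2), cond_row)
  r3 <- c(meta_names, sprintf("S%d", seq_len(ns)))
  body <- cbind(seqs, accessions,
                matrix(as.character(abund), nrow = n))
  if (!is.null(use_in_quant)) {
    r1 <- c(r1, ""); r2 <- c(r2, ""); r3 <- c(r3, "Use in quantitation")
    body <- cbind(body, use_in_quant)
  }
  if (extra_raw) {
    r1 <- c(r1, "Raw abundance", rep("", ns - 1))
    r2 <- c(r2, cond_row)
    r3 <- c(r3, sprintf("S%d", seq_len(ns)))
    body <- cbind(body, matrix(as.character(abund * 2), nrow = n))
  }
  lines <- apply(rbind(r1, r2, r3, body), 1, paste, collapse = delim)
  writeLines(lines, path)
  path
}

# brute-force fully-tryptic oracle: enumerate every digest product directly,
# including the des-Met forms that the N-terminal Met-excision rule admits
brute_force_digest_set <- function(proteins, max_missed,
                                   proline_rule = FALSE) {
  met <- startsWith(proteins$sequence, "M") & nchar(proteins$sequence) > 1L
  clipped <- proteins[met, ]
  clipped$sequence <- substr(clipped$sequence, 2, nchar(clipped$sequence))
  unique(digest_proteome(rbind(proteins, clipped), max_missed,
                         proline_rule)$sequence)
}

# independent slow oracle for "is this substring fully tryptic somewhere":
# check every occurrence's termini directly against the cleavage rules
oracle_fully_tryptic <- function(peptide, proteins, proline_rule = FALSE) {
  any(vapply(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    hits <- stringi::stri_locate_all_fixed(s, peptide, overlap = TRUE)[[1]]
    if (all(is.na(hits[, 1]))) return(FALSE)
    any(apply(hits, 1, function(h) {
      st <- h[1]; en <- h[2]
      prev <- if (st > 1) substr(s, st - 1, st - 1) else "-"
      nxt <- if (en < nchar(s)) substr(s, en + 1, en + 1) else "-"
      frst <- substr(s, st, st); lst <- substr(s, en, en)
      n_ok <- st == 1 || (st == 2 && prev == "M") ||
        (prev %in% c("K", "R") && (!proline_rule || frst != "P"))
      c_ok <- en == nchar(s) ||
        (lst %in% c("K", "R") && (!proline_rule || nxt != "P"))
      n_ok && c_ok
    }))
  }, logical(1)))
}

random_peptides_from <- function(proteins, n, len_range = c(4L, 25L)) {
  seqs <- proteins$sequence
  idx <- sample.int(length(seqs), n, replace = TRUE)
  vapply(idx, function(i) {
    L <- nchar(seqs[i])
    w <- sample(len_range[1]:min(len_range[2], L), 1)
    st <- sample.int(L - w + 1L, 1)
    substr(seqs[i], st, st + w - 1L)
  }, character(1))
}
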