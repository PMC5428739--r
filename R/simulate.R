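# Synthetic proteomes and Progenesis-style measurement exports with planted
# neopeptides, so the whole pipeline is testable without any real data.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a random proteome
#'
#' Random sequences over the 20 standard amino acids with K and R at about
#' 11% combined frequency, so zero-missed tryptic fragments average 8-12
#' residues (as in real proteomes). Fully determined by `seed`.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Inclusive range of protein lengths.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param path Optional FASTA output path (UniProt-style headers).
#' @return A protein tibble in [read_fasta()] layout.
#' @export
simulate_proteome <- function(n_proteins = 50L, length_range = c(80L, 120L),
                              seed = NULL, path = NULL) {
  stopifnot(n_proteins >= 1L)
  if (!is.null(seed)) withr::local_seed(seed)
  prob <- stats::setNames(rep((1 - 0.11) / 18, 20), AA20)
  prob[c("K", "R")] <- 0.055
  len_pool <- seq.int(length_range[1L], length_range[2L])
  lens <- len_pool[sample.int(length(len_pool), n_proteins, replace = TRUE)]
  seqs <- vapply(lens, function(L)
    paste(sample(AA20, L, replace = TRUE, prob = prob), collapse = ""),
    character(1))
  acc <- sprintf("SIM%03d", seq_len(n_proteins))
  proteins <- tibble::tibble(
    header_token = sprintf("sp|%s|%s_SYN", acc, acc),
    bare_accession = acc,
    description = sprintf("Synthetic protein %d", seq_len(n_proteins)),
    sequence = seqs
  )
  if (!is.null(path)) write_fasta(proteins, path)
  proteins
}

# truncate a zero-missed tryptic fragment at an internal position to make a
# guaranteed semi-tryptic peptide (one terminus tryptic, the other not).
# Truncated peptides keep >= 6 residues (the practical lower bound for MS
# identification) and must occur exactly once in the proteome so the planted
# location is the one the annotation will report.
make_semi_candidates <- function(proteins, index) {
  frag <- digest_proteome(proteins, max_missed = 0L) |>
    dplyr::filter(nchar(.data$sequence) >= 10L)
  all_seq <- paste(proteins$sequence, collapse = "-")
  purrr::pmap(frag, function(accession, header_token, sequence, start, end,
                             missed_cleavages) {
    L <- nchar(sequence)
    keep_prefix <- stats::runif(1) < 0.5
    lo <- if (keep_prefix) 6L else 3L
    hi <- if (keep_prefix) L - 3L else L - 6L
    cuts <- seq.int(lo, hi)
    cuts <- cuts[sample.int(length(cuts))]
    for (cut in cuts) {
      if (keep_prefix) {
        pep <- stringr::str_sub(sequence, 1L, cut)
        bad_terminus <- stringr::str_sub(sequence, cut, cut) %in% c("K", "R")
        p_start <- start
        p_end <- start + cut - 1L
      } else {
        pep <- stringr::str_sub(sequence, cut + 1L, L)
        bad_terminus <- stringr::str_sub(sequence, cut, cut) %in% c("K", "R")
        p_start <- start + cut
        p_end <- end
      }
      if (bad_terminus || fast_is_fully_tryptic(pep, index) ||
          stringi::stri_count_fixed(all_seq, pep, overlap = TRUE) != 1L) next
      prot_seq <- proteins$sequence[proteins$bare_accession == accession]
      return(tibble::tibble(
        sequence = pep, accession = accession, start = p_start, end = p_end,
        preceding = if (p_start == 1L) "-"
                    else stringr::str_sub(prot_seq, p_start - 1L, p_start - 1L),
        following = if (p_end == nchar(prot_seq)) "-"
                    else stringr::str_sub(prot_seq, p_end + 1L, p_end + 1L),
        parent_fragment = sequence
      ))
    }
    NULL
  }) |>
    dplyr::bind_rows()
}

#' Simulate a Progenesis-style peptide-measurements CSV with planted truth
#'
#' Builds a three-header-row export over two conditions: fully-tryptic rows
#' from digesting the proteome (no condition effect), `n_null` semi-tryptic
#' "null" neopeptides (fold change 1), and `n_planted` differential
#' neopeptides whose abundance in the second condition is multiplied by
#' `fold_change`. Neopeptides are made by truncating zero-missed tryptic
#' fragments at an internal non-K/R position, guaranteeing semi-tryptic
#' status by construction. Abundances are multiplicative log-normal around
#' per-peptide baselines with coefficient of variation `cv` (the standard
#' noise model for label-free MS intensities). The export carries both a
#' "Normalized abundance" and a "Raw abundance" block, plus Accession,
#' Score, Modifications and "Use in quantitation" columns, exercising
#' layout auto-detection.
#'
#' @param proteins Protein tibble (e.g. from [simulate_proteome()]).
#' @param n_planted Number of differential neopeptides.
#' @param n_null Number of fold-change-1 neopeptides.
#' @param n_per_group Samples per condition.
#' @param fold_change Multiplicative effect on the second condition's
#'   planted rows.
#' @param cv Coefficient of variation of the log-normal measurement noise.
#' @param conditions Two condition labels.
#' @param frac_missed Fraction of extra tryptic rows carrying one missed
#'   cleavage.
#' @param seed Integer seed; fully determines the output.
#' @param path Optional CSV output path.
#' @param truth_path Optional TSV output path for the truth table.
#' @return A list: `table` (all CSV rows as a character tibble), `truth`
#'   (tibble: `sequence`, `accession`, `start`, `end`, `preceding`,
#'   `following`, `type`, `fold_change`), `path`, `truth_path`, `proteins`.
#' @export
simulate_measurements <- function(proteins, n_planted = 3L, n_null = 20L,
                                  n_per_group = 4L, fold_change = 4,
                                  cv = 0.2, conditions = c("CTRL", "TREAT"),
                                  frac_missed = 0.1, seed = NULL,
                                  path = NULL, truth_path = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(length(conditions) == 2L, n_per_group >= 2L)

  index <- build_tryptic_index(proteins, max_missed = 2L)
  frag0 <- digest_proteome(proteins, max_missed = 0L) |>
    dplyr::filter(nchar(.data$sequence) >= 6L, nchar(.data$sequence) <= 30L)
  frag1 <- digest_proteome(proteins, max_missed = 1L) |>
    dplyr::filter(.data$missed_cleavages == 1L,
                  nchar(.data$sequence) >= 6L, nchar(.data$sequence) <= 30L)
  if (nrow(frag1) > 0L && frac_missed > 0) {
    frag1 <- frag1[sample.int(nrow(frag1),
                              max(1L, round(frac_missed * nrow(frag1)))), ]
  } else {
    frag1 <- frag1[0L, ]
  }
  tryptic <- dplyr::bind_rows(frag0, frag1) |>
    dplyr::distinct(.data$accession, .data$sequence, .keep_all = TRUE)

  semis <- make_semi_candidates(proteins, index) |>
    dplyr::distinct(.data$sequence, .keep_all = TRUE)
  semis <- semis[!semis$sequence %in% tryptic$sequence, ]
  need <- n_planted + n_null
  if (nrow(semis) < need) {
    stop("proteome too small: only ", nrow(semis),
         " semi-tryptic candidates for ", need, " requested", call. = FALSE)
  }
  pick <- semis[sample.int(nrow(semis), need), ]
  truth <- dplyr::bind_rows(
    if (n_planted > 0L) dplyr::mutate(pick[seq_len(n_planted), ],
                                      type = "planted",
                                      fold_change = fold_change),
    if (n_null > 0L) dplyr::mutate(pick[n_planted + seq_len(n_null), ],
                                   type = "null", fold_change = 1)
  ) |>
    dplyr::select("sequence", "accession", "start", "end", "preceding",
                  "following", "type", "fold_change")

  # abundances
  nsamp <- 2L * n_per_group
  sdlog <- sqrt(log(1 + cv^2))
  prot_base <- stats::setNames(
    stats::rlnorm(nrow(proteins), meanlog = log(1e6), sdlog = 0.5),
    proteins$bare_accession)
  draw <- function(acc, fold) {
    base <- prot_base[[acc]] * stats::rlnorm(1, 0, 0.3)
    v <- base * stats::rlnorm(nsamp, 0, sdlog)
    v[(n_per_group + 1L):nsamp] <- v[(n_per_group + 1L):nsamp] * fold
    v
  }
  all_rows <- dplyr::bind_rows(
    dplyr::mutate(tryptic[c("sequence", "accession", "header_token")],
                  fold_change = 1, type = "tryptic"),
    dplyr::left_join(truth[c("sequence", "accession", "fold_change", "type")],
                     proteins[c("bare_accession", "header_token")],
                     by = c(accession = "bare_accession"))
  )
  ab <- t(vapply(seq_len(nrow(all_rows)), function(i)
    draw(all_rows$accession[i], all_rows$fold_change[i]), numeric(nsamp)))
  raw_scale <- stats::rlnorm(nsamp, 0, 0.2)
  raw <- sweep(ab, 2L, raw_scale, `*`)

  ord <- sample.int(nrow(all_rows))
  all_rows <- all_rows[ord, ]
  ab <- ab[ord, , drop = FALSE]
  raw <- raw[ord, , drop = FALSE]

  samples <- sprintf("S%d", seq_len(nsamp))
  fmt <- function(m) format(m, trim = TRUE, scientific = FALSE, digits = 10)
  meta <- tibble::tibble(
    Sequence = all_rows$sequence,
    Modifications = "",
    Accession = all_rows$header_token,
    Score = fmt(round(stats::runif(nrow(all_rows), 20, 60), 2)),
    `Use in quantitation` = "True"
  )
  body <- dplyr::bind_cols(
    meta,
    stats::setNames(as_tibble(fmt(ab), .name_repair = "minimal"), samples),
    stats::setNames(as_tibble(fmt(raw), .name_repair = "minimal"),
                    paste0("raw.", samples))
  )

  nmeta <- ncol(meta)
  r1 <- c(rep("", nmeta), "Normalized abundance", rep("", nsamp - 1L),
          "Raw abundance", rep("", nsamp - 1L))
  cond_row <- c(conditions[1L], rep("", n_per_group - 1L),
                conditions[2L], rep("", n_per_group - 1L))
  r2 <- c(rep("", nmeta), cond_row, cond_row)
  r3 <- c(names(meta), samples, samples)
  tab <- dplyr::bind_rows(
    stats::setNames(as_tibble(rbind(r1, r2, r3), .name_repair = "minimal"),
                    names(body)),
    body
  )

  if (!is.null(path)) {
    readr::write_delim(tab, path, delim = ",", col_names = FALSE,
                       quote = "needed", escape = "double", na = "")
  }
  if (!is.null(truth_path)) readr::write_tsv(truth, truth_path)

  list(table = tab, truth = truth, path = path, truth_path = truth_path,
       proteins = proteins)
}
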