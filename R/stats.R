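# Parent-protein normalization and two-condition differential testing.
#
# Normalizing a neopeptide's abundance to the summed abundance of its parent
# protein's fully-tryptic peptides removes protein-level abundance changes,
# so that a differential normalized value reflects a change in the EXTENT of
# native cleavage, not in how much parent protein was present.

#' Normalize a neopeptide to its parent's tryptic abundance
#'
#' Per sample, the normalized value is the semi-tryptic (neopeptide)
#' abundance divided by the sum of the abundances of all the parent
#' protein's fully-tryptic peptide rows in that sample. The value is missing
#' where the denominator is zero or any contributing cell is missing.
#' Parents with fewer than `min_peptides` distinct fully-tryptic peptide
#' sequences are excluded entirely (returns `NULL`).
#'
#' @param neopeptide Numeric abundance vector of the semi-tryptic row
#'   (aligned to sample columns).
#' @param tryptic Numeric matrix of the parent's fully-tryptic rows
#'   (rows = peptide rows, columns = the same samples). Duplicate sequences
#'   and charge states all contribute to the sum.
#' @param min_peptides Minimum number of distinct fully-tryptic peptide
#'   sequences required to trust the denominator.
#' @param tryptic_sequences Optional character vector (one per `tryptic`
#'   row) used to count distinct sequences; defaults to treating each row as
#'   distinct.
#' @return A numeric vector of normalized values with attribute
#'   `n_tryptic_peptides`, or `NULL` when excluded by `min_peptides`.
#' @examples
#' normalize_neopeptide(c(5, 8), rbind(c(10, 10), c(40, 30)))
#' @export
normalize_neopeptide <- function(neopeptide, tryptic, min_peptides = 1L,
                                 tryptic_sequences = NULL) {
  tryptic <- matrix(as.numeric(tryptic), ncol = length(neopeptide))
  n_seq <- if (is.null(tryptic_sequences)) nrow(tryptic)
           else dplyr::n_distinct(tryptic_sequences)
  if (n_seq < min_peptides) return(NULL)
  den <- colSums(tryptic) # NA propagates: any missing cell voids the sample
  val <- neopeptide / den
  val[!is.finite(val)] <- NA_real_
  structure(val, n_tryptic_peptides = n_seq)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classic two-sided two-sample t-test with pooled variance and
#' `n_a + n_b - 2` degrees of freedom, computed in closed form. Missing
#' values are removed first; with fewer than two values in either group, or
#' with zero pooled variance and equal means (a degenerate comparison with
#' no principled finite statistic), the p-value is missing with a reason
#' code. `welch = TRUE` switches to the unequal-variance Welch test.
#'
#' @param a,b Numeric vectors for the two conditions.
#' @param welch Use Welch's unequal-variance test instead?
#' @return A list: `p_value`, `statistic`, `df`, `reason` (`NA` when a
#'   p-value was produced).
#' @examples
#' t_test_pooled(c(1, 2), c(3, 4))$p_value # ~0.106
#' @export
t_test_pooled <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2L || nb < 2L) {
    return(list(p_value = NA_real_, statistic = NA_real_, df = NA_real_,
                reason = "too-few-values"))
  }
  if (welch) {
    ht <- stats::t.test(a, b)
    return(list(p_value = unname(ht$p.value),
                statistic = unname(ht$statistic),
                df = unname(ht$parameter), reason = NA_character_))
  }
  df <- na + nb - 2L
  sp2 <- ((na - 1L) * stats::var(a) + (nb - 1L) * stats::var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (d == 0) {
      return(list(p_value = NA_real_, statistic = NA_real_, df = df,
                  reason = "degenerate"))
    }
    return(list(p_value = 0, statistic = sign(d) * Inf, df = df,
                reason = NA_character_))
  }
  tt <- d / sqrt(sp2 * (1 / na + 1 / nb))
  list(p_value = 2 * stats::pt(-abs(tt), df), statistic = tt, df = df,
       reason = NA_character_)
}

#' Bonferroni pass flag
#'
#' `TRUE` when `p < alpha / m`, the Bonferroni-corrected threshold for a
#' family of `m` tests at level `alpha`. A missing p-value never passes.
#'
#' @param p Numeric vector of raw p-values (NA allowed).
#' @param m Family size (tests with a defined p-value).
#' @param alpha Significance level (the user-supplied "FDR" of the original
#'   interface).
#' @return Logical vector.
#' @export
bonferroni_pass <- function(p, m, alpha = 0.05) {
  stopifnot(m >= 1L, alpha > 0, alpha <= 1)
  !is.na(p) & p < alpha / m
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH procedure: p-values sorted ascending, `p_i * m / rank_i`,
#' monotonicity enforced by a cumulative minimum from the largest rank, and
#' capped at 1. Missing entries pass through as missing and do not count
#' toward the family size `m`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  ok <- !is.na(p)
  m <- sum(ok)
  out <- rep(NA_real_, length(p))
  if (m == 0L) return(out)
  q <- p[ok]
  o <- order(q, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(q[o] * m / seq.int(m, 1L)))[ro]
  out
}

# group tryptic rows by parent accession. Grouping uses the export's
# reported accession (bare form) so the fast dictionary path -- which never
# learns a tryptic row's location -- and the slow scan give identical
# results; rows without a usable reported accession fall back to the
# annotation's chosen protein.
tryptic_groups <- function(annotations, reported) {
  acc <- reported
  fallback <- is.na(acc) | !nzchar(acc)
  acc[fallback] <- annotations$accession[fallback]
  acc
}

#' Normalize and test all neopeptides of a measurement table
#'
#' For every semi-tryptic (neopeptide) row: the parent protein is the
#' annotation's chosen location; the denominator is the per-sample sum over
#' all rows classified fully tryptic that carry the parent's accession;
#' normalized values are compared between the two detected conditions with
#' a Student's t-test; and the family of defined p-values is corrected with
#' Bonferroni (pass flag at `alpha/m`) and Benjamini-Hochberg.
#'
#' @param x A `progenesis_data` object from [read_progenesis()] (must carry
#'   a two-condition design with at least two samples per condition).
#' @param annotations Tibble from [annotate_peptides()] aligned to the data
#'   rows of `x`.
#' @param proteins Protein table ([read_fasta()]); needed only for
#'   `matching_only`.
#' @param alpha Significance level for the Bonferroni flag.
#' @param min_peptides Minimum distinct fully-tryptic sequences a parent
#'   needs; parents below it are excluded with a message.
#' @param log_transform Log2-transform normalized values before testing
#'   (non-positive values dropped per sample)?
#' @param matching_only Restrict denominator rows to those whose sequence is
#'   verified present in the parent protein's sequence (guards against stale
#'   accession assignments in the export)?
#' @param welch Use Welch's t-test instead of the pooled Student's test?
#' @param test Compute p-values? Set `FALSE` to produce normalized values
#'   only (used when no two-condition design exists).
#' @param quiet Suppress messages?
#' @return A `neopeptide_results` tibble, one row per retained neopeptide in
#'   input row order: `row`, `accession`, `peptide`, `preceding`,
#'   `following`, `n_tryptic_peptides`, per-sample `norm_*` columns,
#'   per-condition `mean_*` columns, and (when tested) `p_value`, `reason`,
#'   `bf_pass`, `bh_p`. Attributes: `alpha`, `m`, `sample_names`,
#'   `conditions`, `input_path`, `delimiter`.
#' @export
analyse_neopeptides <- function(x, annotations, proteins = NULL,
                                alpha = 0.05, min_peptides = 1L,
                                log_transform = FALSE, matching_only = FALSE,
                                welch = FALSE, test = TRUE, quiet = FALSE) {
  stopifnot(inherits(x, "progenesis_data"),
            nrow(annotations) == nrow(x$data))
  design <- x$design
  conds <- unique(design$condition)
  if (test) {
    ok_design <- length(conds) == 2L &&
      all(table(design$condition) >= 2L)
    if (!ok_design) {
      stop("statistical testing needs exactly two conditions with at least ",
           "two samples each; found ", length(conds), call. = FALSE)
    }
  }

  ab <- abundance_matrix(x)
  samples <- x$layout$sample_names
  peptides <- peptide_sequences(x)
  status <- annotations$status

  tryp_idx <- which(status == "tryptic")
  group_acc <- tryptic_groups(annotations, reported_accessions(x))
  semi_idx <- which(status == "semi-tryptic")

  if (matching_only && !is.null(proteins)) {
    parent_seq <- stats::setNames(proteins$sequence, proteins$bare_accession)
  }

  n_excluded <- 0L
  rows <- purrr::map(semi_idx, function(i) {
    parent <- annotations$accession[i]
    t_rows <- tryp_idx[group_acc[tryp_idx] == parent &
                         !is.na(group_acc[tryp_idx])]
    if (matching_only && !is.null(proteins) && length(t_rows) &&
        parent %in% names(parent_seq)) {
      keep <- stringi::stri_detect_fixed(parent_seq[[parent]],
                                         peptides[t_rows])
      t_rows <- t_rows[keep]
    }
    norm <- normalize_neopeptide(ab[i, ], ab[t_rows, , drop = FALSE],
                                 min_peptides = min_peptides,
                                 tryptic_sequences = peptides[t_rows])
    if (is.null(norm)) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    tibble::tibble(
      row = i,
      accession = parent,
      peptide = peptides[i],
      preceding = annotations$preceding[i],
      following = annotations$following[i],
      n_tryptic_peptides = attr(norm, "n_tryptic_peptides"),
      norm = list(stats::setNames(as.numeric(norm), samples))
    )
  })
  res <- dplyr::bind_rows(rows)
  if (n_excluded > 0L) {
    log_msg(quiet, n_excluded, " neopeptide(s) excluded: parent has fewer ",
            "than ", min_peptides, " distinct tryptic peptide sequence(s)")
  }
  if (nrow(res) == 0L) {
    res <- tibble::tibble(row = integer(), accession = character(),
                          peptide = character(), preceding = character(),
                          following = character(),
                          n_tryptic_peptides = integer(),
                          norm = list())
  }

  norm_mat <- do.call(rbind, c(res$norm, list(matrix(numeric(0), 0,
                                                     length(samples)))))
  test_mat <- norm_mat
  if (log_transform && nrow(test_mat)) {
    test_mat[!is.na(test_mat) & test_mat <= 0] <- NA_real_
    test_mat <- log2(test_mat)
  }

  out <- res[setdiff(names(res), "norm")]
  for (k in seq_along(samples)) {
    out[[paste0("norm_", samples[k])]] <-
      if (nrow(out)) norm_mat[, k] else numeric(0)
  }

  if (nrow(design)) {
    cols_by_cond <- split(match(design$sample, samples), design$condition)
    cols_by_cond <- cols_by_cond[conds] # preserve appearance order
    for (cn in conds) {
      out[[paste0("mean_", cn)]] <- if (nrow(out)) {
        rowMeans(test_mat[, cols_by_cond[[cn]], drop = FALSE], na.rm = TRUE)
      } else numeric(0)
    }
  }

  if (test) {
    ga <- cols_by_cond[[conds[1L]]]
    gb <- cols_by_cond[[conds[2L]]]
    tests <- purrr::map(seq_len(nrow(out)), function(r)
      t_test_pooled(test_mat[r, ga], test_mat[r, gb], welch = welch))
    out$p_value <- purrr::map_dbl(tests, "p_value")
    out$reason <- purrr::map_chr(tests, "reason")
    m <- sum(!is.na(out$p_value))
    out$bf_pass <- if (m >= 1L) bonferroni_pass(out$p_value, m, alpha)
                   else logical(nrow(out))
    out$bh_p <- bh_adjust(out$p_value)
    attr(out, "m") <- m
  } else {
    attr(out, "m") <- 0L
  }

  attr(out, "alpha") <- alpha
  attr(out, "sample_names") <- samples
  attr(out, "conditions") <- conds
  attr(out, "input_path") <- x$path
  attr(out, "delimiter") <- x$delimiter
  attr(out, "n_excluded_min_peptides") <- n_excluded
  class(out) <- c("neopeptide_results", class(out))
  out
}

#' @export
print.neopeptide_results <- function(x, ...) {
  cat("<neopeptide_results> ", nrow(x), " neopeptides",
      if (!is.null(attr(x, "m"))) paste0(", ", attr(x, "m"), " tested"),
      "\n", sep = "")
  NextMethod()
}
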