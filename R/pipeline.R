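#' Run the full neopeptide discovery pipeline
#'
#' End-to-end analysis of one Progenesis QIP peptide-measurements export
#' against a FASTA proteome: parse with layout auto-detection, infer the
#' missed-cleavage setting from the data, locate and classify every peptide
#' (optionally pre-screening with the fast tryptic dictionary), write the
#' annotated copy of the input, then normalize the semi-tryptic neopeptides
#' to parent-protein tryptic abundance, test the two conditions, correct for
#' multiple testing, and write the processed neopeptide file.
#'
#' With `fast_lookup = TRUE`, peptides found in the tryptic dictionary skip
#' the proteome scan (their flank cells are left empty in the annotated
#' file, as the dictionary cannot supply flanks); semi-tryptic candidates
#' always get the full scan, so the processed file is identical either way.
#'
#' @param input Path to the peptide-measurements CSV.
#' @param fasta Path to the protein database FASTA.
#' @param output Annotated output path (default: input stem +
#'   `"_with_filter.csv"`).
#' @param processed Processed output path (default: input stem +
#'   `"_processed.csv"`).
#' @param alpha Significance level for the Bonferroni flag (the interface's
#'   user-supplied "FDR").
#' @param min_peptides Minimum distinct fully-tryptic sequences a parent
#'   protein needs for its neopeptides to be quantified.
#' @param fast_lookup Pre-screen fully-tryptic peptides with the dictionary?
#' @param proline_rule Suppress cleavage before proline?
#' @param data_field Abundance block to analyse (see [detect_layout()]).
#' @param use_in_quantitation Apply the "use in quantitation" filter before
#'   any analysis?
#' @param log_transform Log2-transform normalized values before testing?
#' @param matching_only Restrict denominators to tryptic rows verified
#'   present in the parent sequence?
#' @param delimiter,peptide_column Optional format overrides.
#' @param welch Use Welch's t-test instead of pooled Student's?
#' @param quiet Suppress the per-stage log messages?
#' @return An object of class `neopeptide_analysis` (list with
#'   `annotations`, `results`, `design`, `counts`, `paths`, `options`),
#'   invisibly printable, with [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @examples
#' \donttest{
#' fa <- tempfile(fileext = ".fasta")
#' csv <- tempfile(fileext = ".csv")
#' prot <- simulate_proteome(15, seed = 1, path = fa)
#' simulate_measurements(prot, seed = 2, path = csv)
#' fit <- neopeptide_run(csv, fa, quiet = TRUE)
#' glance(fit)
#' }
#' @export
neopeptide_run <- function(input, fasta, output = NULL, processed = NULL,
                           alpha = 0.05, min_peptides = 1L,
                           fast_lookup = FALSE, proline_rule = FALSE,
                           data_field = NULL, use_in_quantitation = FALSE,
                           log_transform = FALSE, matching_only = FALSE,
                           delimiter = NULL, peptide_column = NULL,
                           welch = FALSE, quiet = FALSE) {
  proteins <- read_fasta(fasta)
  log_msg(quiet, "read ", nrow(proteins), " proteins from ", fasta)

  px <- read_progenesis(input, delimiter = delimiter,
                        data_field = data_field,
                        peptide_column = peptide_column, quiet = quiet)
  log_msg(quiet, "read ", nrow(px$data), " peptide rows (",
          px$n_skipped, " skipped) from ", input)
  if (use_in_quantitation) px <- filter_use_in_quantitation(px, quiet = quiet)

  peptides <- peptide_sequences(px)
  mc <- infer_missed_cleavages(peptides, proline_rule)
  log_msg(quiet, "missed cleavages inferred from data: ", mc)

  if (fast_lookup) {
    index <- build_tryptic_index(proteins, max_missed = mc,
                                 proline_rule = proline_rule)
    pre <- fast_is_fully_tryptic(peptides, index)
    annotations <- tibble::tibble(
      peptide = peptides, status = NA_character_, n_occurrences = NA_integer_,
      accession = NA_character_, header_token = NA_character_,
      start = NA_integer_, end = NA_integer_,
      preceding = NA_character_, following = NA_character_
    )
    annotations$status[pre] <- "tryptic"
    if (any(!pre)) {
      slow <- annotate_peptides(peptides[!pre], proteins, proline_rule)
      annotations[!pre, names(slow)] <- slow
    }
    log_msg(quiet, "fast dictionary pre-screen: ", sum(pre),
            " fully-tryptic peptides skipped the proteome scan")
  } else {
    annotations <- annotate_peptides(peptides, proteins, proline_rule)
  }

  tab <- table(factor(annotations$status, levels = status_levels))
  log_msg(quiet, "classified: ", tab[["tryptic"]], " tryptic, ",
          tab[["semi-tryptic"]], " semi-tryptic (neopeptides), ",
          tab[["non-tryptic"]], " non-tryptic, ",
          tab[["not-found"]], " not found in database")

  output <- output %||% default_output_path(input, "with_filter")
  write_annotated(px, annotations, output)
  log_msg(quiet, "annotated file written: ", output)

  conds <- unique(px$design$condition)
  two_cond <- length(conds) == 2L && all(table(px$design$condition) >= 2L)
  if (!two_cond) {
    warning("did not detect exactly two conditions with >=2 samples each; ",
            "statistics skipped", call. = FALSE)
  }
  results <- analyse_neopeptides(
    px, annotations, proteins = proteins, alpha = alpha,
    min_peptides = min_peptides, log_transform = log_transform,
    matching_only = matching_only, welch = welch, test = two_cond,
    quiet = quiet
  )
  processed <- processed %||% default_output_path(input, "processed")
  write_processed(results, processed)
  log_msg(quiet, "processed neopeptide file written: ", processed)

  m <- attr(results, "m")
  counts <- tibble::tibble(
    rows_read = nrow(px$data) + px$n_skipped,
    rows_skipped = px$n_skipped,
    n_tryptic = unname(tab[["tryptic"]]),
    n_semi_tryptic = unname(tab[["semi-tryptic"]]),
    n_non_tryptic = unname(tab[["non-tryptic"]]),
    n_not_found = unname(tab[["not-found"]]),
    n_excluded_min_peptides = attr(results, "n_excluded_min_peptides"),
    n_neopeptides = nrow(results),
    n_tested = m,
    bf_passes = if (two_cond) sum(results$bf_pass, na.rm = TRUE) else NA_integer_,
    bh_significant = if (two_cond) sum(results$bh_p < alpha, na.rm = TRUE)
                     else NA_integer_,
    alpha = alpha
  )
  if (two_cond) {
    log_msg(quiet, "tested ", m, " neopeptides: ", counts$bf_passes,
            " pass Bonferroni at alpha/m, ", counts$bh_significant,
            " have BH-adjusted p < ", alpha)
  }

  structure(
    list(annotations = annotations, results = results, design = px$design,
         layout = px$layout, counts = counts,
         paths = list(input = input, fasta = fasta, output = output,
                      processed = processed),
         options = list(alpha = alpha, min_peptides = min_peptides,
                        fast_lookup = fast_lookup,
                        proline_rule = proline_rule,
                        log_transform = log_transform,
                        matching_only = matching_only, welch = welch,
                        missed_cleavages = mc)),
    class = "neopeptide_analysis"
  )
}

#' @export
print.neopeptide_analysis <- function(x, ...) {
  cat("<neopeptide_analysis>\n")
  cat("  input:    ", x$paths$input, "\n", sep = "")
  cat("  database: ", x$paths$fasta, "\n", sep = "")
  with(x$counts, cat(
    "  rows: ", rows_read, " read; ", n_tryptic, " tryptic, ",
    n_semi_tryptic, " semi-tryptic, ", n_non_tryptic, " non-tryptic, ",
    n_not_found, " not found\n",
    "  neopeptides: ", n_neopeptides, " quantified, ", n_tested,
    " tested; ", bf_passes, " BF passes, ", bh_significant,
    " BH-significant at alpha = ", alpha, "\n", sep = ""))
  invisible(x)
}

#' Tidy the per-neopeptide results of an analysis
#'
#' @param x A `neopeptide_analysis` object.
#' @param ... Unused.
#' @return The `neopeptide_results` tibble (one row per quantified
#'   neopeptide).
#' @method tidy neopeptide_analysis
#' @export
tidy.neopeptide_analysis <- function(x, ...) {
  out <- x$results
  class(out) <- setdiff(class(out), "neopeptide_results")
  out
}

#' One-row summary of an analysis
#'
#' @param x A `neopeptide_analysis` object.
#' @param ... Unused.
#' @return A one-row tibble of stage counts (rows read and skipped, tryptic
#'   status tallies, neopeptides quantified/tested, Bonferroni passes and
#'   BH-significant calls at the chosen alpha).
#' @method glance neopeptide_analysis
#' @export
glance.neopeptide_analysis <- function(x, ...) {
  x$counts
}

#' Volcano plot of neopeptide differential abundance
#'
#' Log2 ratio of condition means of the normalized neopeptide values
#' against -log10 raw p-value, coloured by BH significance at the analysis
#' alpha.
#'
#' @param object A `neopeptide_analysis` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot neopeptide_analysis
#' @export
autoplot.neopeptide_analysis <- function(object, ...) {
  res <- object$results
  if (!"p_value" %in% names(res) || nrow(res) == 0L) {
    stop("no test results to plot", call. = FALSE)
  }
  conds <- attr(res, "conditions")
  alpha <- attr(res, "alpha")
  df <- tibble::tibble(
    ratio = log2(res[[paste0("mean_", conds[2L])]] /
                   res[[paste0("mean_", conds[1L])]]),
    p = res$p_value,
    significant = !is.na(res$bh_p) & res$bh_p < alpha
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
      name = paste0("BH < ", alpha)) +
    ggplot2::labs(
      x = paste0("log2 normalized abundance ratio (", conds[2L], " / ",
                 conds[1L], ")"),
      y = "-log10 p-value",
      title = "Neopeptide differential abundance") +
    ggplot2::theme_minimal()
}

#' Volcano plot shortcut
#' @inheritParams autoplot.neopeptide_analysis
#' @param x A `neopeptide_analysis` object.
#' @return A ggplot object.
#' @export
plot_neopeptides <- function(x, ...) autoplot(x, ...)
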