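# Progenesis QIP "peptide measurements" CSV input and the two output files.
#
# The export has three header rows: row 1 labels the abundance blocks
# ("Normalized abundance", "Raw abundance", ...) at the block's first
# column, row 2 carries the condition labels spanning their sample columns
# (spanned cells are blank), row 3 names every column (metadata columns and
# per-sample names). Data rows follow, one per peptide ion. Files may have
# been round-tripped through Excel, so parsing is RFC-4180 with BOM
# tolerance and the delimiter is auto-detected.

#' Detect the field delimiter of a delimited text file
#'
#' Tries comma, semicolon and tab and picks the candidate giving the highest
#' consistent field count across the sampled lines (ties broken in that
#' order).
#'
#' @param lines Character vector with the first few lines of the file.
#' @return A single delimiter character.
#' @export
detect_delimiter <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("cannot detect delimiter: no input text",
                                call. = FALSE)
  cands <- c(",", ";", "\t")
  score <- vapply(cands, function(d) {
    counts <- stringi::stri_count_fixed(lines, d) + 1L
    tab <- table(counts)
    modal <- as.integer(names(tab)[which.max(tab)])
    # quoted cells may embed the delimiter, so require only a majority of
    # lines to agree on the field count
    if (modal >= 2L && max(tab) / length(counts) >= 0.6) modal else 0L
  }, integer(1))
  if (all(score < 2L)) {
    stop("cannot detect delimiter: no candidate yields at least 2 fields",
         call. = FALSE)
  }
  cands[which.max(score)]
}

# decide layout from the all-character parsed rows
detect_layout_impl <- function(raw, data_field = NULL, peptide_column = NULL,
                               quiet = FALSE) {
  ncol <- ncol(raw)
  cells <- function(i) as.character(unlist(raw[i, ], use.names = FALSE))
  r1 <- cells(1L)

  three_header <- nrow(raw) >= 4L &&
    !any(is_numeric_like(cells(1L))) && !any(is_numeric_like(cells(2L)))
  header_rows <- if (three_header) 3L else 1L
  if (!three_header) {
    warning("fewer than 3 header rows detected; falling back to ",
            "single-header mode (no condition information)", call. = FALSE)
  }
  names_row <- cells(header_rows)
  data <- raw[-seq_len(header_rows), , drop = FALSE]
  if (nrow(data) == 0L) stop("no data rows found", call. = FALSE)

  # numeric columns: >=95% of data cells numeric or blank, >=1 numeric
  col_cells <- lapply(seq_len(ncol), function(j)
    as.character(unlist(data[, j], use.names = FALSE)))
  is_num <- vapply(col_cells, function(x) {
    nonblank <- x[!is.na(x) & x != ""]
    length(nonblank) > 0L && mean(is_numeric_like(nonblank)) >= 0.95
  }, logical(1))

  # peptide column: every data cell an amino-acid-only string
  aa_col <- vapply(col_cells, function(x) {
    all(!is.na(x) & stringr::str_detect(x, "^[A-Z]+$")) &&
      stats::median(nchar(x)) >= 4
  }, logical(1))
  if (is.null(peptide_column)) {
    cand <- which(aa_col & !is_num)
    if (length(cand) == 0L) {
      stop("cannot find peptide column (no column contains only ",
           "amino-acid strings)", call. = FALSE)
    }
    if (length(cand) > 1L) {
      named <- cand[stringr::str_detect(names_row[cand],
                                        stringr::regex("seq|peptide",
                                                       ignore_case = TRUE))]
      cand <- if (length(named)) named else cand
    }
    peptide_column <- cand[1L]
  }

  # abundance block under the chosen data-field label
  if (three_header) {
    lab <- ffill_chr(stringr::str_trim(r1))
    fields <- unique(stringr::str_trim(r1[!is.na(r1) & nzchar(stringr::str_trim(r1))]))
    if (is.null(data_field)) {
      norm <- fields[stringr::str_detect(fields, stringr::regex("normali",
                                                                ignore_case = TRUE))]
      data_field <- if (length(norm)) norm[1L] else fields[1L]
    } else if (!tolower(data_field) %in% tolower(fields)) {
      stop("data field '", data_field, "' not found; available: ",
           paste(fields, collapse = ", "), call. = FALSE)
    } else {
      data_field <- fields[match(tolower(data_field), tolower(fields))]
    }
    in_field <- tolower(lab) == tolower(data_field) & is_num
  } else {
    data_field <- NA_character_
    in_field <- is_num
  }
  runs <- rle(in_field)
  if (!any(runs$values)) {
    stop("cannot find a numeric abundance block",
         if (!is.na(data_field)) paste0(" under data field '", data_field, "'"),
         call. = FALSE)
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  block <- seq.int(starts[best], ends[best])

  # experiment design from the condition row, forward-filled within the block
  if (three_header) {
    cond <- ffill_chr(stringr::str_trim(cells(2L)[block]))
    design <- tibble::tibble(column = block,
                             sample = names_row[block],
                             condition = cond)
    if (any(!nzchar(design$condition))) {
      warning("sample column(s) without a condition label dropped from the ",
              "design", call. = FALSE)
      design <- design[nzchar(design$condition), ]
    }
  } else {
    design <- tibble::tibble(column = block, sample = names_row[block],
                             condition = character(length(block)))[0, ]
  }

  find_col <- function(pattern) {
    hit <- which(stringr::str_detect(names_row,
                                     stringr::regex(pattern, ignore_case = TRUE)))
    if (length(hit)) hit[1L] else NA_integer_
  }

  list(
    layout = list(
      header_rows = header_rows,
      peptide_column = as.integer(peptide_column),
      accession_column = find_col("accession"),
      modifications_column = find_col("modification"),
      use_in_quantitation_column = find_col("use.?in.?quant"),
      abundance_block = block,
      data_field = data_field,
      sample_names = names_row[block]
    ),
    design = design
  )
}

#' Detect the layout of a Progenesis-style measurement table
#'
#' Identifies the peptide-sequence column (all cells amino-acid-only
#' strings), the numeric abundance block belonging to the requested data
#' field, and the two-condition experiment design from the spanning labels
#' of the condition header row.
#'
#' @param raw A data frame of character cells, header rows included (as read
#'   with all-character columns).
#' @param data_field Abundance-block label to use (e.g. `"Normalized
#'   abundance"` or `"Raw abundance"`); default: the block whose label
#'   matches "normali", else the first labelled block.
#' @param peptide_column Optional 1-based column index override.
#' @return A list with elements `layout` (delimiter-independent column map)
#'   and `design` (tibble: `column`, `sample`, `condition`).
#' @export
detect_layout <- function(raw, data_field = NULL, peptide_column = NULL) {
  detect_layout_impl(raw, data_field = data_field,
                     peptide_column = peptide_column)
}

#' Read a Progenesis QIP peptide-measurements CSV
#'
#' Parses the export with layout auto-detection. All original cells are
#' preserved verbatim as character (for lossless pass-through to the
#' annotated output); abundances are parsed on demand by
#' [abundance_matrix()]. Blank abundance cells are missing, literal zeros
#' stay `0`. Rows whose field count disagrees with the header are skipped
#' with a logged line number; more than 10% skipped rows is an error.
#'
#' @param path Path to the CSV export.
#' @param delimiter Field delimiter; default auto-detect via
#'   [detect_delimiter()].
#' @inheritParams detect_layout
#' @param quiet Suppress progress messages?
#' @return An object of class `progenesis_data`: a list with `header` (the
#'   header rows, character), `data` (data rows, character, passthrough),
#'   `layout`, `design`, `delimiter`, `path`, `n_skipped`.
#' @export
read_progenesis <- function(path, delimiter = NULL, data_field = NULL,
                            peptide_column = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  delim <- delimiter %||% detect_delimiter(readr::read_lines(path, n_max = 10))
  raw <- suppressWarnings(readr::read_delim(
    path, delim = delim, col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = FALSE, progress = FALSE,
    show_col_types = FALSE
  ))
  prob <- readr::problems(raw)
  bad_rows <- integer(0)
  if (nrow(prob) > 0L) {
    bad <- prob[stringr::str_detect(prob$expected, "columns"), , drop = FALSE]
    bad_rows <- sort(unique(bad$row))
  }
  n_data_total <- nrow(raw)
  if (length(bad_rows)) {
    if (length(bad_rows) / n_data_total > 0.10) {
      stop("more than 10% of rows have an inconsistent field count in ",
           path, call. = FALSE)
    }
    log_msg(quiet, "skipping ", length(bad_rows),
            " row(s) with inconsistent field count (lines: ",
            paste(utils::head(bad_rows, 10L), collapse = ", "),
            if (length(bad_rows) > 10L) ", ..." else "", ")")
    raw <- raw[-bad_rows, , drop = FALSE]
  }
  raw[is.na(raw)] <- ""

  det <- detect_layout_impl(raw, data_field = data_field,
                            peptide_column = peptide_column, quiet = quiet)
  hr <- det$layout$header_rows
  structure(
    list(
      path = path,
      delimiter = delim,
      header = raw[seq_len(hr), , drop = FALSE],
      data = raw[-seq_len(hr), , drop = FALSE],
      layout = det$layout,
      design = det$design,
      n_skipped = length(bad_rows),
      skipped_rows = bad_rows
    ),
    class = "progenesis_data"
  )
}

#' @export
print.progenesis_data <- function(x, ...) {
  cat("<progenesis_data> ", nrow(x$data), " peptide rows, ",
      length(x$layout$abundance_block), " sample columns ('",
      x$layout$data_field %||% "?", "')\n", sep = "")
  if (nrow(x$design)) {
    tab <- table(x$design$condition)
    cat("  conditions: ",
        paste(names(tab), " (n=", tab, ")", sep = "", collapse = ", "), "\n",
        sep = "")
  } else {
    cat("  conditions: none detected\n")
  }
  invisible(x)
}

#' Peptide sequences of a measurement table
#' @param x A `progenesis_data` object.
#' @return Character vector, one sequence per data row.
#' @export
peptide_sequences <- function(x) {
  as.character(unlist(x$data[, x$layout$peptide_column], use.names = FALSE))
}

#' Reported accessions of a measurement table (bare form)
#' @param x A `progenesis_data` object.
#' @return Character vector (NA-filled when the export has no accession
#'   column), normalized with [read_fasta()]'s bare-accession rule.
#' @export
reported_accessions <- function(x) {
  j <- x$layout$accession_column
  if (is.na(j)) return(rep(NA_character_, nrow(x$data)))
  bare_accession(as.character(unlist(x$data[, j], use.names = FALSE)))
}

#' Numeric abundance matrix of a measurement table
#'
#' @param x A `progenesis_data` object.
#' @return Numeric matrix, rows = peptide rows, columns = the samples of the
#'   detected abundance block (named by sample). Blank or non-numeric cells
#'   are `NA`; zeros are kept as `0`.
#' @export
abundance_matrix <- function(x) {
  block <- x$layout$abundance_block
  m <- vapply(block, function(j)
    parse_abundance(as.character(unlist(x$data[, j], use.names = FALSE))),
    numeric(nrow(x$data)))
  m <- matrix(m, nrow = nrow(x$data),
              dimnames = list(NULL, x$layout$sample_names))
  m
}

#' Apply the "use in quantitation" filter
#'
#' Drops rows whose use-in-quantitation cell is false-like ("false", "no",
#' "0", "n"). A no-op (with a message) when the export has no such column.
#'
#' @param x A `progenesis_data` object.
#' @param quiet Suppress messages?
#' @return The filtered `progenesis_data` object.
#' @export
filter_use_in_quantitation <- function(x, quiet = FALSE) {
  j <- x$layout$use_in_quantitation_column
  if (is.na(j)) {
    log_msg(quiet, "no 'use in quantitation' column found; filter skipped")
    return(x)
  }
  v <- tolower(stringr::str_trim(
    as.character(unlist(x$data[, j], use.names = FALSE))))
  drop <- v %in% c("false", "no", "0", "n")
  if (any(drop)) {
    log_msg(quiet, "'use in quantitation' filter removed ", sum(drop),
            " row(s)")
    x$data <- x$data[!drop, , drop = FALSE]
  }
  x
}

default_output_path <- function(input, suffix) {
  paste0(tools::file_path_sans_ext(input), "_", suffix, ".csv")
}

#' Write the annotated ("with_filter") output file
#'
#' Reproduces the input file cell-for-cell and appends exactly three
#' columns: the preceding residue, the following residue, and the tryptic
#' status of each peptide. Not-found peptides get empty flank cells.
#'
#' @param x A `progenesis_data` object.
#' @param annotations Tibble from [annotate_peptides()], one row per data
#'   row of `x`.
#' @param path Output path; default: input file stem + `"_with_filter.csv"`.
#' @return The output path, invisibly.
#' @export
write_annotated <- function(x, annotations, path = NULL) {
  stopifnot(nrow(annotations) == nrow(x$data))
  path <- path %||% default_output_path(x$path, "with_filter")
  hr <- nrow(x$header)
  blank <- function(v) ifelse(is.na(v), "", v)

  extra_header <- matrix("", nrow = hr, ncol = 3L)
  extra_header[hr, ] <- c("Preceding residue", "Following residue",
                          "Tryptic status")
  extra_data <- cbind(blank(annotations$preceding),
                      blank(annotations$following),
                      annotations$status)
  out <- dplyr::bind_rows(x$header, x$data)
  add <- rbind(extra_header, extra_data)
  out$..preceding <- add[, 1L]
  out$..following <- add[, 2L]
  out$..status <- add[, 3L]
  readr::write_delim(out, path, delim = x$delimiter, col_names = FALSE,
                     quote = "needed", escape = "double", na = "")
  invisible(path)
}

#' Write the neopeptide ("processed") output file
#'
#' One row per retained neopeptide: parent protein accession, sequence,
#' flanking residues, per-sample normalized abundances, per-condition means,
#' raw p-value, Bonferroni pass flag at `alpha/m`, and BH-adjusted p-value.
#' When statistics were skipped (no two-condition design) the p-value
#' columns are simply absent.
#'
#' @param results A `neopeptide_results` tibble from
#'   [analyse_neopeptides()].
#' @param path Output path; default: input file stem + `"_processed.csv"`.
#' @param delimiter Field delimiter for the output (default: the input
#'   file's).
#' @return The output path, invisibly.
#' @export
write_processed <- function(results, path = NULL, delimiter = NULL) {
  input <- attr(results, "input_path")
  path <- path %||% default_output_path(input %||% "neopeptides", "processed")
  delimiter <- delimiter %||% attr(results, "delimiter") %||% ","
  samples <- attr(results, "sample_names")

  out <- tibble::tibble(
    Accession = results$accession,
    Sequence = results$peptide,
    `Preceding residue` = results$preceding,
    `Following residue` = results$following,
    `Tryptic peptides` = results$n_tryptic_peptides
  )
  for (s in samples) {
    out[[paste("Normalized", s)]] <- results[[paste0("norm_", s)]]
  }
  mean_cols <- grep("^mean_", names(results), value = TRUE)
  for (mc in mean_cols) {
    out[[paste("Mean", sub("^mean_", "", mc))]] <- results[[mc]]
  }
  if ("p_value" %in% names(results)) {
    out$`p-value` <- results$p_value
    out$`BF pass` <- results$bf_pass
    out$`BH adjusted p-value` <- results$bh_p
  }
  if (nrow(out) == 0L) {
    warning("no neopeptides to write; writing header-only file to ", path,
            call. = FALSE)
  }
  readr::write_delim(out, path, delim = delimiter, quote = "needed",
                     escape = "double", na = "")
  invisible(path)
}
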