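test_that("detect_delimiter picks the consistent candidate", {
  expect_equal(detect_delimiter(c("a,b,c", "d,e,f")), ",")
  expect_equal(detect_delimiter("a;b;c"), ";")
  expect_equal(detect_delimiter(c("a\tb", "c\td")), "\t")
  expect_error(detect_delimiter("one_field_only"), "delimiter")
})

test_that("round trip through each delimiter preserves detection", {
  for (d in c(",", ";", "\t")) {
    path <- write_tmp_progenesis(c("ACDEK", "LMNPQ"),
                                 matrix(1:8, 2), delim = d)
    expect_equal(detect_delimiter(readLines(path)), d)
    px <- read_progenesis(path, quiet = TRUE)
    expect_equal(peptide_sequences(px), c("ACDEK", "LMNPQ"))
  }
})

test_that("layout detection finds peptide column, block and conditions", {
  path <- write_tmp_progenesis(c("ACDEK", "LMNPQ", "WYSTR"),
                               matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
                                      nrow = 3),
                               conditions = c("CTRL", "IL1B"))
  px <- read_progenesis(path, quiet = TRUE)
  expect_equal(px$layout$peptide_column, 1L)
  expect_equal(length(px$layout$abundance_block), 4L)
  expect_equal(px$design$condition, c("CTRL", "CTRL", "IL1B", "IL1B"))
  expect_equal(px$design$sample, sprintf("S%d", 1:4))
})

test_that("layout detection survives a reordered sequence column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    ",,,Normalized abundance,,,",
    ",,,A,,B,",
    "Score,Accession,Sequence,S1,S2,S3,S4",
    "31.5,sp|P1|X,ACDEK,1,2,3,4",
    "44.1,sp|P2|Y,LMNPQ,5,6,7,8"
  ), path)
  px <- read_progenesis(path, quiet = TRUE)
  expect_equal(px$layout$peptide_column, 3L)
  expect_equal(px$layout$abundance_block, 4:7)
  expect_equal(reported_accessions(px), c("P1", "P2"))
})

test_that("the data-field option selects between abundance blocks", {
  path <- write_tmp_progenesis(c("ACDEK", "LMNPQ"), matrix(1:8, 2),
                               extra_raw = TRUE)
  norm <- read_progenesis(path, quiet = TRUE)
  raw <- read_progenesis(path, data_field = "Raw abundance", quiet = TRUE)
  expect_equal(norm$layout$data_field, "Normalized abundance")
  expect_equal(raw$layout$data_field, "Raw abundance")
  expect_equal(abundance_matrix(raw), abundance_matrix(norm) * 2)
  expect_error(read_progenesis(path, data_field = "Bogus", quiet = TRUE),
               "not found")
})

test_that("quoted thousands separators and blanks parse correctly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    ",Normalized abundance,,,",
    ",A,,B,",
    "Sequence,S1,S2,S3,S4",
    'ACDEK,"1,234.5",2,,0',
    "LMNPQ,5,6,7,8"
  ), path)
  px <- read_progenesis(path, quiet = TRUE)
  ab <- abundance_matrix(px)
  expect_equal(ab[1, ], c(S1 = 1234.5, S2 = 2, S3 = NA, S4 = 0))
  # blank is missing, zero is zero
  expect_true(is.na(ab[1, 3]) && ab[1, 4] == 0)
})

test_that("rows with inconsistent field counts are skipped, >10% is fatal", {
  path <- withr::local_tempfile(fileext = ".csv")
  good <- paste0("PEP", strrep("A", 1:20), "K,", 1:20, ",", 21:40,
                 ",", 41:60, ",", 61:80)
  lines <- c(",Normalized abundance,,,", ",A,,B,", "Sequence,S1,S2,S3,S4",
             good[1:10], "BROKENROW,1,2", good[11:20])
  writeLines(lines, path)
  expect_message(px <- read_progenesis(path), "skipping 1 row")
  expect_equal(nrow(px$data), 20L)
  expect_equal(px$n_skipped, 1L)

  writeLines(c(",Normalized abundance,,,", ",A,,B,", "Sequence,S1,S2,S3,S4",
               good[1:3], rep("BAD,1", 3)), path)
  expect_error(suppressWarnings(read_progenesis(path, quiet = TRUE)),
               "10%")
})

test_that("single-header files fall back with a warning and no design", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sequence,S1,S2", "ACDEK,1,2", "LMNPQ,3,4"), path)
  expect_warning(px <- read_progenesis(path, quiet = TRUE),
                 "single-header")
  expect_equal(nrow(px$design), 0L)
  expect_equal(px$layout$abundance_block, 2:3)
})

test_that("use-in-quantitation filter drops false-like rows", {
  path <- write_tmp_progenesis(c("ACDEK", "LMNPQ", "WYSTR"),
                               matrix(1:12, 3),
                               use_in_quant = c("True", "False", "True"))
  px <- read_progenesis(path, quiet = TRUE)
  expect_message(fx <- filter_use_in_quantitation(px), "removed 1")
  expect_equal(peptide_sequences(fx), c("ACDEK", "WYSTR"))
})

test_that("annotated output is input plus exactly three columns, row order kept", {
  prot <- protein_tbl("MACDKEFGRHILK")
  fasta <- write_tmp_fasta(prot)
  path <- write_tmp_progenesis(c("EFGR", "HIL", "WWWW"), matrix(1:12, 3),
                               accessions = rep("P1", 3))
  px <- read_progenesis(path, quiet = TRUE)
  ann <- annotate_peptides(peptide_sequences(px), prot)
  out <- withr::local_tempfile(fileext = ".csv")
  write_annotated(px, ann, out)

  orig <- strsplit(readLines(path), ",")
  got <- strsplit(readLines(out), ",")
  expect_equal(length(got), length(orig))
  for (i in seq_along(orig)) {
    expect_equal(length(got[[i]]), length(orig[[i]]) + 3L)
    expect_equal(got[[i]][seq_along(orig[[i]])], orig[[i]])
  }
  last <- vapply(got[-(1:3)], function(x) x[length(x)], "")
  expect_equal(last, c("tryptic", "semi-tryptic", "not-found"))
  # not-found rows have empty flank cells
  expect_equal(got[[6]][7:8], c("", ""))
})

test_that("default output names derive from the input stem", {
  dir <- withr::local_tempdir()
  input <- file.path(dir, "pep.csv")
  expect_equal(neopeptider:::default_output_path(input, "with_filter"),
               file.path(dir, "pep_with_filter.csv"))
  expect_equal(neopeptider:::default_output_path(input, "processed"),
               file.path(dir, "pep_processed.csv"))
})

test_that("write_processed emits the documented columns, header-only when empty", {
  prot <- protein_tbl(c("MMMAAKCDEFGHKRRR"))
  fasta <- write_tmp_fasta(prot)
  path <- write_tmp_progenesis(
    c("CDEFGHK", "CDEF", "AAK"),
    matrix(c(10, 20, 30, 12, 22, 32, 11, 21, 31, 13, 23, 33), nrow = 3),
    accessions = rep("P1", 3))
  px <- read_progenesis(path, quiet = TRUE)
  ann <- annotate_peptides(peptide_sequences(px), prot)
  res <- analyse_neopeptides(px, ann, prot, quiet = TRUE)
  out <- withr::local_tempfile(fileext = ".csv")
  write_processed(res, out)
  tab <- readr::read_csv(out, show_col_types = FALSE)
  expect_true(all(c("Accession", "Sequence", "Preceding residue",
                    "Following residue", "p-value", "BF pass",
                    "BH adjusted p-value") %in% names(tab)))
  expect_true(all(sprintf("Normalized S%d", 1:4) %in% names(tab)))
  expect_equal(nrow(tab), sum(ann$status == "semi-tryptic"))

  empty <- res[0, ]
  attr(empty, "input_path") <- path
  attr(empty, "sample_names") <- attr(res, "sample_names")
  expect_warning(write_processed(empty, out), "header-only")
  expect_equal(nrow(readr::read_csv(out, show_col_types = FALSE)), 0L)
})
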