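test_that("normalization divides by the summed tryptic abundance", {
  v <- normalize_neopeptide(c(5, 8), rbind(c(10, 10), c(40, 30)))
  expect_equal(as.numeric(v), c(0.1, 0.2))
  expect_equal(attr(v, "n_tryptic_peptides"), 2L)

  # zero denominator and missing cells void the sample, not the peptide
  v2 <- normalize_neopeptide(c(5, 8, 2), rbind(c(10, 0, NA), c(40, 0, 5)))
  expect_equal(as.numeric(v2), c(0.1, NA, NA))

  # below min_peptides: excluded entirely
  expect_null(normalize_neopeptide(c(5, 8), rbind(c(10, 10)),
                                   min_peptides = 2))
  expect_null(normalize_neopeptide(c(5, 8), rbind(c(1, 1), c(2, 2)),
                                   min_peptides = 2,
                                   tryptic_sequences = c("AK", "AK")))
})

test_that("pooled t-test matches the closed form and handles degeneracy", {
  expect_equal(t_test_pooled(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  tt <- t_test_pooled(c(1, 2), c(3, 4))
  expect_equal(tt$statistic, -2.828, tolerance = 1e-3)
  expect_equal(tt$df, 2)
  expect_equal(tt$p_value, 0.10557, tolerance = 1e-4)

  deg <- t_test_pooled(c(5, 5), c(5, 5))
  expect_true(is.na(deg$p_value))
  expect_equal(deg$reason, "degenerate")

  few <- t_test_pooled(1, c(2, 3))
  expect_true(is.na(few$p_value))
  expect_equal(few$reason, "too-few-values")

  sep <- t_test_pooled(c(5, 5), c(7, 7))
  expect_equal(sep$p_value, 0)
})

test_that("pooled t-test agrees with stats::t.test on random samples", {
  set.seed(100)
  for (i in 1:300) {
    a <- rnorm(sample(2:6, 1))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -1, 1))
    ref <- t.test(a, b, var.equal = TRUE)
    got <- t_test_pooled(a, b)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("t-test is symmetric in labels and shift-invariant", {
  set.seed(101)
  for (i in 1:50) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(t_test_pooled(a, b)$p_value, t_test_pooled(b, a)$p_value)
    expect_equal(t_test_pooled(a, b)$p_value,
                 t_test_pooled(a + 3, b + 3)$p_value)
  }
})

test_that("bonferroni_pass applies the alpha/m threshold", {
  expect_true(bonferroni_pass(0.0004, 100, 0.05))
  expect_false(bonferroni_pass(0.001, 100, 0.05))
  expect_true(bonferroni_pass(0.04, 1, 0.05))
  expect_false(bonferroni_pass(NA_real_, 10, 0.05))
  expect_error(bonferroni_pass(0.01, 0, 0.05))
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_adjust matches stats::p.adjust on random vectors", {
  set.seed(102)
  for (i in 1:300) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
})

test_that("BH is monotone, dominates raw p, and is implied by Bonferroni", {
  set.seed(103)
  for (i in 1:30) {
    p <- runif(25)^2
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_equal(order(adj[order(p)]), seq_along(p)) # order preserved
    bf <- bonferroni_pass(p, length(p), 0.05)
    expect_true(all(adj[bf] < 0.05)) # BF pass implies BH-significant
  }
})

make_analysis_fixture <- function(seed, n_proteins = 12, n_planted = 3,
                                  n_null = 10, fold_change = 4, ...) {
  prot <- simulate_proteome(n_proteins, c(80, 120), seed = seed)
  fasta <- tempfile(fileext = ".fasta")
  csv <- tempfile(fileext = ".csv")
  write_fasta(prot, fasta)
  sim <- simulate_measurements(prot, n_planted = n_planted, n_null = n_null,
                               fold_change = fold_change,
                               seed = seed + 1000L, path = csv, ...)
  list(prot = prot, fasta = fasta, csv = csv, truth = sim$truth)
}

test_that("analyse recovers planted effects and leaves nulls alone", {
  fx <- make_analysis_fixture(2001)
  px <- read_progenesis(fx$csv, quiet = TRUE)
  ann <- annotate_peptides(peptide_sequences(px), fx$prot)
  res <- analyse_neopeptides(px, ann, fx$prot, quiet = TRUE)
  planted <- fx$truth$sequence[fx$truth$type == "planted"]
  hit <- res[res$peptide %in% planted, ]
  expect_equal(nrow(hit), 3L)
  expect_true(all(hit$bh_p < 0.05))
  # planted direction: condition 2 mean above condition 1 mean
  expect_true(all(hit$mean_TREAT > hit$mean_CTRL))
  unlink(c(fx$fasta, fx$csv))
})

test_that("normalization is invariant to per-sample scaling of a protein", {
  fx <- make_analysis_fixture(2002)
  px <- read_progenesis(fx$csv, quiet = TRUE)
  ann <- annotate_peptides(peptide_sequences(px), fx$prot)
  res1 <- analyse_neopeptides(px, ann, fx$prot, quiet = TRUE)

  # multiply every abundance of one parent protein in one sample by 17
  parent <- res1$accession[1]
  acc <- reported_accessions(px)
  rows <- which(acc == parent)
  j <- px$layout$abundance_block[2]
  cells <- as.numeric(unlist(px$data[rows, j]))
  px$data[rows, j] <- as.character(cells * 17)
  res2 <- analyse_neopeptides(px, ann, fx$prot, quiet = TRUE)

  norm_cols <- grep("^norm_", names(res1), value = TRUE)
  keep <- res1$accession == parent
  expect_equal(as.data.frame(res1[keep, norm_cols]),
               as.data.frame(res2[keep, norm_cols]),
               tolerance = 1e-12)
  unlink(c(fx$fasta, fx$csv))
})

test_that("min_peptides gates on distinct tryptic sequences", {
  prot <- protein_tbl("MMMAAKCDEFGHKRRR")
  path <- write_tmp_progenesis(
    c("CDEFGHK", "CDEF"),
    matrix(c(10, 30, 12, 32, 11, 31, 13, 33), nrow = 2),
    accessions = rep("P1", 2))
  px <- read_progenesis(path, quiet = TRUE)
  ann <- annotate_peptides(peptide_sequences(px), prot)
  res1 <- analyse_neopeptides(px, ann, prot, min_peptides = 1, quiet = TRUE)
  expect_equal(nrow(res1), 1L)
  expect_equal(res1$n_tryptic_peptides, 1L)
  expect_message(
    res2 <- analyse_neopeptides(px, ann, prot, min_peptides = 2),
    "excluded")
  expect_equal(nrow(res2), 0L)
})

test_that("single neopeptide family gives bh equal to raw p", {
  prot <- protein_tbl("MMMAAKCDEFGHKRRR")
  path <- write_tmp_progenesis(
    c("CDEFGHK", "CDEF"),
    matrix(c(10, 5, 12, 6, 30, 14, 33, 16), nrow = 2),
    accessions = rep("P1", 2))
  px <- read_progenesis(path, quiet = TRUE)
  ann <- annotate_peptides(peptide_sequences(px), prot)
  res <- analyse_neopeptides(px, ann, prot, quiet = TRUE)
  expect_equal(attr(res, "m"), 1L)
  expect_equal(res$bh_p, res$p_value)
})

test_that("all-equal abundances give p = 1 or missing and no BF passes", {
  prot <- protein_tbl("MMMAAKCDEFGHKRRR")
  path <- write_tmp_progenesis(
    c("CDEFGHK", "CDEF", "AAK"),
    matrix(5, nrow = 3, ncol = 4),
    accessions = rep("P1", 3))
  px <- read_progenesis(path, quiet = TRUE)
  ann <- annotate_peptides(peptide_sequences(px), prot)
  res <- analyse_neopeptides(px, ann, prot, quiet = TRUE)
  expect_true(all(is.na(res$p_value) | res$p_value == 1))
  expect_false(any(res$bf_pass))
})

test_that("log-transform drops non-positive values and changes the scale", {
  fx <- make_analysis_fixture(2003)
  px <- read_progenesis(fx$csv, quiet = TRUE)
  ann <- annotate_peptides(peptide_sequences(px), fx$prot)
  res <- analyse_neopeptides(px, ann, fx$prot, log_transform = TRUE,
                             quiet = TRUE)
  planted <- fx$truth$sequence[fx$truth$type == "planted"]
  hit <- res[res$peptide %in% planted, ]
  # log2 mean difference near log2(4) = 2 for planted rows
  expect_equal(unname(hit$mean_TREAT - hit$mean_CTRL), rep(2, nrow(hit)),
               tolerance = 0.5)
  unlink(c(fx$fasta, fx$csv))
})

test_that("analysis refuses designs without two usable conditions", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",Normalized abundance,,,",
               ",A,,,",
               "Sequence,S1,S2,S3,S4",
               "ACDEK,1,2,3,4"), path)
  px <- read_progenesis(path, quiet = TRUE)
  ann <- annotate_peptides("ACDEK", protein_tbl("AAKACDEKAA"))
  expect_error(analyse_neopeptides(px, ann, quiet = TRUE),
               "two conditions")
  # but normalization-only mode still works
  res <- analyse_neopeptides(px, ann, test = FALSE, quiet = TRUE)
  expect_false("p_value" %in% names(res))
})
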