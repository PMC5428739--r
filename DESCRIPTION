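Package: neopeptider
Title: Neopeptide Discovery in Label-Free Proteomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies semi-tryptic 'neopeptides' -- peptides with at least
    one terminus produced by native (in vivo) proteolysis rather than by the
    trypsin used in sample preparation -- in peptide-level label-free
    quantification exports such as the Progenesis QIP peptide measurements
    CSV. Peptides are located in a FASTA proteome, annotated with their
    flanking residues and tryptic status (with edge rules for protein
    termini and N-terminal methionine excision), normalized to the summed
    abundance of their parent protein's fully-tryptic peptides, and tested
    for differential abundance between two conditions with Bonferroni and
    Benjamini-Hochberg multiple-testing correction. Includes an in-silico
    trypsin digestion engine with missed cleavages, a fast tryptic-peptide
    dictionary, a synthetic-data generator with planted neopeptides for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
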