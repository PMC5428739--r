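# neopeptider

Neopeptide discovery in label-free proteomics data.

In shotgun proteomics, trypsin cleaves proteins after lysine (K) and
arginine (R), so ordinary peptides have two trypsin-consistent termini. A
**neopeptide** is a peptide with exactly one such terminus — a
*semi-tryptic* peptide — whose other end was created by a protease acting
*in vivo*. In cartilage, tendon and other connective tissues these native
cleavage products report on extracellular-matrix turnover and are candidate
disease biomarkers. `neopeptider` finds them in peptide-level label-free
quantification exports (the Progenesis QIP "peptide measurements" CSV),
annotates them against a FASTA proteome, and tests them for differential
abundance between two conditions.

For each measured peptide the package:

1. locates every exact occurrence in the database and classifies each
   terminus (protein terminus, position 2 behind an initiator Met, or a K/R
   boundary count as tryptic), preferring a fully tryptic location when the
   sequence occurs in several proteins;
2. reports the residues flanking the chosen location and the tryptic status
   in an annotated copy of the input (`*_with_filter.csv` — input columns
   verbatim plus exactly three new ones);
3. normalizes each neopeptide's abundance per sample to the summed
   abundance of its parent protein's fully-tryptic peptides,
   x̃ᵢₛ = xᵢₛ / Σⱼ∈tryptic(Pᵢ) xⱼₛ, so changes reflect the extent of native
   cleavage rather than protein-level change;
4. compares the two conditions with a pooled-variance Student's t-test and
   reports, across the family of m tested neopeptides, a Bonferroni pass
   flag at α/m and Benjamini–Hochberg adjusted p-values
   (`*_processed.csv`).

An exact dictionary of all fully-tryptic peptides (with missed cleavages
inferred from the data) provides an O(1) fast pre-screen for large files;
semi-tryptic candidates always get the full scan, so the processed output
is identical either way. A seeded simulator
(`simulate_proteome()` / `simulate_measurements()`) generates
Progenesis-style fixtures with planted neopeptides of known fold change for
validation.

## Worked example

```r
library(neopeptider)

prot <- simulate_proteome(15, seed = 1, path = "example.fasta")
sim  <- simulate_measurements(prot, seed = 2, path = "example.csv")

fit <- neopeptide_run("example.csv", "example.fasta", log_transform = TRUE)
#> read 15 proteins from example.fasta
#> read 131 peptide rows (0 skipped) from example.csv
#> missed cleavages inferred from data: 1
#> classified: 108 tryptic, 23 semi-tryptic (neopeptides), 0 non-tryptic, 0 not found in database
#> annotated file written: example_with_filter.csv
#> processed neopeptide file written: example_processed.csv
#> tested 23 neopeptides: 3 pass Bonferroni at alpha/m, 3 have BH-adjusted p < 0.05

tidy(fit) |>
  dplyr::arrange(bh_p) |>
  dplyr::select(accession, peptide, preceding, following, p_value, bf_pass, bh_p)
#> # A tibble: 23 × 7
#>   accession peptide  preceding following   p_value bf_pass    bh_p
#>   <chr>     <chr>    <chr>     <chr>         <dbl> <lgl>     <dbl>
#> 1 SIM005    LHYEFMIM K         A         0.0000789 TRUE    0.00181
#> 2 SIM008    SNYYGEV  A         -         0.000443  TRUE    0.00510
#> 3 SIM011    NQYIGL   K         D         0.00119   TRUE    0.00913
#> 4 SIM006    QHADLGR  G         C         0.0651    FALSE   0.361
#> 5 SIM008    YVNQGNC  R         V         0.0784    FALSE   0.361
#> # ℹ 18 more rows
```

The three BH-significant rows are exactly the three neopeptides the
simulator planted with a 4-fold abundance change (`sim$truth`): each is a
tryptic fragment truncated at an internal non-K/R position, here e.g.
`LHYEFMIM` preceded by `K` (a tryptic N-terminus) and followed by `A` (the
native-cleavage side). `glance(fit)` gives the one-row stage summary and
`autoplot(fit)` a volcano plot of log2 normalized ratio against −log10 p.

The same pipeline is available from a shell:

```sh
exec/neopeptide run --input example.csv --fasta example.fasta --log-transform
exec/neopeptide simulate --seed 1 --fasta db.fasta --output pep.csv
```

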