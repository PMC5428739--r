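---
title: "Neopeptide discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neopeptide discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neopeptider)
```

## The problem

Shotgun proteomics digests proteins with trypsin, which cleaves after lysine
(K) and arginine (R). A peptide whose termini are both explained by trypsin
is ordinary; a peptide with exactly one tryptic terminus — a *semi-tryptic*
peptide, or **neopeptide** — carries evidence that the other terminus was
created by a protease acting *in vivo*, before the sample ever met trypsin.
In connective-tissue biology such native cleavage products are read-outs of
matrix turnover and candidate disease biomarkers, so finding them reliably
in label-free quantification (LFQ) exports, and testing whether their
abundance differs between conditions, is the whole point of this package.

The input is a peptide-measurements table as exported by Progenesis QIP
(three header rows: abundance-block labels, condition labels, per-sample
column names; one data row per peptide ion) together with the FASTA protein
database the identifications were searched against.

## Classifying a peptide

Every measured sequence is located exactly (all occurrences, overlapping
included) in every database protein. At each occurrence:

* the **N-terminus is tryptic** if the peptide starts the protein
  (position 1), starts at position 2 behind an initiator methionine
  (N-terminal Met excision is near-universal in vivo, so it is not evidence
  of native cleavage), or is preceded by K or R;
* the **C-terminus is tryptic** if the peptide ends the protein or its last
  residue is K or R.

Both termini tryptic → `tryptic`; exactly one → `semi-tryptic` (a
neopeptide); neither → `non-tryptic`; no occurrence anywhere → `not-found`.
When a sequence occurs in several proteins, a fully tryptic location is
preferred over a semi-tryptic one (the conservative reading: if an ordinary
tryptic origin exists, it is the likelier source); among equal-status
locations the first in database order wins, which keeps the output
deterministic. The chosen location supplies the two flanking residues
reported next to each peptide (`-` at a protein terminus).

An optional proline rule (no cleavage before P, for Mascot-style
specificity) is available but **off** by default: plain K/R specificity is
the default classification. Non-standard residue codes (B, J, O, U, X, Z)
are accepted as ordinary letters.

## The fast dictionary path

Scanning the proteome for every peptide is linear in database size, so for
large exports an exact dictionary of all fully-tryptic peptides (up to the
missed-cleavage count inferred from the data — the maximum number of
internal K/R sites over all input peptides) supports O(1) membership tests.
Two subtleties keep the dictionary equivalent to the slow scan:

* proteins starting with methionine contribute the digest products of their
  des-Met form as well, so Met-excision peptides are recognised;
* the dictionary can only answer *is this fully tryptic?* — it cannot supply
  flanking residues, so semi-tryptic candidates always get the full scan.
  Consequently the processed (neopeptide) output is byte-identical with and
  without the fast path; only the annotated file differs, in that
  dictionary-confirmed rows have empty flank cells.

## Normalization

A neopeptide can change in abundance simply because its parent protein
does. To isolate the *extent of native cleavage*, each neopeptide's
abundance in each sample is divided by the summed abundance, in the same
sample, of all rows classified fully tryptic for the parent protein:

$$\tilde{x}_{is} \;=\; \frac{x_{is}}{\sum_{j \in \mathrm{tryptic}(P_i)} x_{js}}$$

Duplicate sequences and charge states all contribute to the denominator.
Tryptic rows are grouped to a parent by the export's accession column
(normalized so `sp|P12345|NAME` and `P12345` match), falling back to the
FASTA-derived assignment when the export has no accession column; this is
what makes the fast and slow paths agree exactly. The optional
"matching peptides only" filter additionally verifies that each denominator
row's sequence occurs in the parent sequence, guarding against stale
accessions in hand-edited exports. A `min_peptides` threshold (default 1)
excludes neopeptides whose parent has too few *distinct* fully-tryptic
sequences to give a trustworthy denominator.

A normalized value is missing when the numerator is missing, any
denominator cell is missing, or the denominator is zero. Blank abundance
cells are *missing*, literal zeros are zeros — Progenesis emits 0 for
absent features, and conflating the two would silently bias the sums.

## Statistics

With exactly two conditions detected in the header (each with at least two
samples), each neopeptide's normalized values are compared with a
two-sided, pooled-variance Student's t-test (df $= n_a + n_b - 2$),
computed in closed form; Welch's unequal-variance variant is available
behind a flag. Degenerate comparisons — fewer than two values in a group,
or zero pooled variance with equal means — yield a missing p-value with a
reason code and are excluded from the correction family.

Across the family of $m$ neopeptides with a defined p-value the package
reports, at the user-chosen level $\alpha$ (default 0.05):

* a **Bonferroni pass flag**, true when $p < \alpha/m$ — simple and very
  conservative for large families;
* the **Benjamini–Hochberg adjusted p-value** (step-up: sort ascending,
  $p_i m / \mathrm{rank}_i$, cumulative minimum from the largest rank,
  capped at 1) — the preferred error control for discovery proteomics.

Both are implemented directly from their definitions and are cross-checked
in the test suite against `stats::p.adjust(method = "BH")` and
`stats::t.test(var.equal = TRUE)` to within $10^{-12}$.

The optional `log_transform` flag tests $\log_2$ of the normalized values
(dropping non-positive values per sample). LFQ intensity noise is
multiplicative, so the log scale makes group variances comparable; on the
raw ratio scale a 4-fold effect also inflates that group's variance
16-fold, which costs real power at small $n$. The package-level validation
experiments therefore run the differential test on the log scale, while the
tool default remains untransformed values, matching the original
interface's opt-in behaviour.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | level for the Bonferroni flag and BH significance |
| `min_peptides` | 1 | distinct tryptic sequences a parent needs |
| `proline_rule` | off | suppress cleavage before proline |
| `fast_lookup` | off | dictionary pre-screen for fully-tryptic rows |
| `log_transform` | off | test log2 normalized values |
| `matching_only` | off | verify denominator rows occur in the parent |
| `use_in_quantitation` | off | honour the export's boolean filter column |
| `data_field` | auto | which abundance block to analyse ("Normalized abundance" preferred) |
| `delimiter`, `peptide_column` | auto | format overrides |

Layout auto-detection mirrors the behaviour users rely on in practice: the
peptide column is the one whose cells are all amino-acid-only strings
(header names like "Sequence" break ties), the abundance block is the
maximal contiguous numeric run under the chosen data-field label, and
condition labels are forward-filled across the blank spanned cells of the
condition header row. Files that lost their extra header rows (e.g. after
an Excel round-trip) fall back to single-header parsing with a warning;
without a two-condition design the annotated and processed files are still
written, minus the p-value columns. Rows whose field count disagrees with
the header are skipped with logged line numbers; more than 10% such rows
aborts the run. Parsing is RFC-4180 (quoted fields, doubled quotes, BOM
tolerated) and the annotated output reproduces every input cell verbatim,
adding exactly three columns.

## The synthetic-data generator

`simulate_proteome()` draws random sequences over the 20 standard amino
acids with K+R at ~11% combined frequency, so zero-missed tryptic fragments
average 8–12 residues as in real proteomes. `simulate_measurements()`
builds a faithful Progenesis-style export: fully-tryptic rows from the
digest (lengths 6–30, a fraction with one missed cleavage), plus
neopeptides made by truncating a zero-missed fragment at an internal
non-K/R position — semi-tryptic *by construction*, at least 6 residues
(the practical identification floor), and required to occur exactly once
in the proteome so the recorded truth location is unambiguous. Abundances
are per-peptide log-normal baselines with multiplicative log-normal noise
(default CV 0.2, the standard LFQ noise model); planted neopeptides are
multiplied by the fold change in the second condition only. Everything is
deterministic under a seed.

The generator emulates the *format* and the *noise structure* of real
exports, not the physics: there are no missing features, no retention-time
or charge-state effects, no identification errors, no correlated
sample-level batch factors, and null peptides are exactly null. Passing
tests therefore demonstrate that the algorithmic pipeline is correct and
calibrated under its stated noise model — not that any particular real
dataset will behave as cleanly.

## Validation experiments (what the tests compute)

The acceptance suite runs, at sizes chosen to exercise the code paths
thoroughly while staying quick on one CPU: fast-vs-slow agreement on 20
proteomes of 50 proteins (~2,000 peptides each, 100% agreement required);
digestion tiling and closed-form fragment counts ((c+1−m) fragments at
exactly m missed cleavages) plus brute-force dictionary equivalence; a
~30-row hand-built table of terminus edge cases; BH and t-test agreement
with the `stats::` references over 1,000 random instances each; type-I
error calibration over ≥1,000 null neopeptide tests (raw p < 0.05 within
the 3-sigma binomial band of 5%); and recovery of 3 planted 4-fold
neopeptides (CV 0.2, n = 4 per group, 20 nulls) — sequence, parent, both
flanks and BH < 0.05 — in at least 95 of 100 seeded studies.
`scripts/acceptance.R` re-runs the same experiments from scratch at a
user-supplied seed.

## Known limitations

* Exact string matching only: I/L are distinct, modifications are ignored
  when locating (the plain sequence column is matched), and no
  probabilistic protein inference is attempted.
* Only trypsin specificity is modelled; Lys-C, chymotrypsin etc. are out of
  scope.
* Statistics are defined for exactly two conditions; multi-condition
  designs get annotation and normalization only.
* Missing abundances are never imputed; a sample simply drops out of the
  affected test.
* The `m` used for correction counts neopeptides with a defined p-value —
  degenerate rows neither gain nor spend multiple-testing budget.
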