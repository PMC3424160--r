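---
title: "Methods: small-RNA cleaning, miRNA discovery, digital expression and target prediction in jellymir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA cleaning, miRNA discovery, digital expression and target prediction in jellymir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jellymir)
```

jellymir reimplements, over synthetic data with complete truth tables, a
comparative analysis of miRNAs in royal jelly from two honey bee species
and of the transcriptomes of bees reared on each jelly. This vignette is
the package's account of the science: the models, their assumptions, the
tunable parameters, and the design choices made where the procedure was
genuinely open.

## Read cleaning

Raw small-RNA reads are assigned exactly one category, evaluated in a
fixed order that matches the accounting table's column order:
`low_quality` → `adapter3_null` → `insert_null` →
`adapter5_contaminant` → `too_short` → `polyA` → `clean`. The rules:

* **low_quality** — mean Phred below 20 or any `N` (`quality_rule()`;
  both configurable). Sequencing pipelines report only a "low-quality"
  discard without defining it, so this default is an explicit assumption
  of the package.
* **adapter3_null** — the 3' adapter does not occur in the read, so the
  insert cannot be delimited. An insert longer than `max_len` (default
  44 nt, the upper edge of the gel size selection) is treated the same
  way: the adapter was not found inside the expected window.
* **insert_null** — the 3' adapter occurs at position 1 (an adapter
  dimer) or the read is empty: there is no insert. We follow the field
  semantics of the two columns — "adapter null" means the *adapter* is
  missing, "insert null" means the *insert* is — which also keeps the
  empty-read degenerate case well defined.
* **adapter5_contaminant** — the trimmed insert contains the 5' adapter.
* **too_short** — trimmed insert below `min_len` (default 18 nt).
* **polyA** — trimmed insert at least 90% A (`polyA_frac`, configurable;
  no published threshold exists for this class).

High-quality reads are the reads surviving the quality rule; the six
remaining categories partition them exactly, and all percentages are
reported against the high-quality total, half-up rounded to two decimals
to match the printed style of the original accounting tables
(`round_half_up()`; base R's `round()` rounds half to even).

Insert-length distributions over the 10–44 nt window are compared with
Pearson's chi-square on the 2×K contingency table of nonzero-combined
bins, without continuity correction (`chi2_length_test()`); proportional
histograms therefore give a statistic of exactly 0.

Singleton removal ("single-read sequences") happens at the tag level:
`collapse_tags()` drops tags whose *total* copy number across the two
libraries falls below `min_count` (default 2), not at the read level.

## Tag mapping and annotation

`map_tags()` searches both strands with substitution-only matching
(Biostrings) at `max_mismatch = 1` and applies best-stratum reporting:
when a tag has any perfect locus its 1-mismatch loci are suppressed —
the standard seed-and-verify convention. Every reported locus is
re-verified by direct comparison, and the whole mapper is checked in the
tests against an exhaustive all-window Hamming scan.

Annotation precedence is `miRNA > rRNAetc > unann`: a catalog-identical
sequence (T/U-insensitive) is miRNA regardless of where it maps; a tag
whose best locus overlaps an rRNA feature is `rRNAetc`; everything else
is unannotated, with unmapped tags flagged separately but folded into
`unann` in the class summary, since the published class table has no
unmapped row. Multi-locus tags count once in unique summaries and their
reads are never split across classes.

In memory, features live in 1-based closed `GRanges` — the R/Bioconductor
idiom — while the BED-like TSV writer emits 0-based half-open coordinates
per the BED convention and the GFF3 writer 1-based ones. This is the
package's own convention for reconciling the two coordinate cultures.

## The energy model and the folding dynamic program

The published pipeline delegated folding to an external engine; jellymir
instead defines a compact, fully specified surrogate (`energy_model()`)
so that every energy is exactly reproducible and testable by brute
force. A secondary structure is scored by loop decomposition:

* a stacked pair contributes the stacking energy keyed by its 5'-most
  pair: GC/CG −3.0, AU/UA −2.0, GU/UG −1.0 kcal/mol;
* a hairpin loop costs a flat +4.0 kcal/mol and must contain at least
  `min_loop = 3` unpaired bases;
* bulges cost +3.0 and internal loops +2.0 kcal/mol per unpaired
  nucleotide;
* multibranch loops are charged as internal loops (per unpaired
  nucleotide inside the loop), and dangling ends and coaxial stacking
  are ignored — documented simplifications relative to a full
  nearest-neighbour parameter set;
* exterior bases are free and the empty structure scores 0, so the MFE
  is never positive.

`fold_mfe()` minimises this energy exactly over all non-crossing
structures with a Zuker-style dynamic program in C++ (paired, multiloop
and exterior matrices; interior loops enumerated without a size cap so
the DP and the explicit evaluator agree on every structure). Tie-breaks
fall to the first optimum in a fixed scan order, making folds
deterministic. `structure_energy()` evaluates any explicit dot-bracket
under the same model; the test suite uses it to score exhaustively
enumerated structures for sequences up to 25 nt (a few thousand to tens
of thousands of structures per sequence) and confirms the DP equals the
enumeration on 500 random cases, as well as auditing that the returned
dot-bracket scores exactly the returned MFE.

With these parameters, a hairpin needs roughly seven GC stacks (or a
correspondingly longer mixed stem) before its energy crosses the
−20 kcal/mol candidate threshold, so the planted 26-pair stems sit far
below the cutoff (around −50 to −70) while short accidental stems do
not — the property the threshold is meant to capture.

## miRNA candidate criteria

A mapped tag of mature length (20–22 nt by default) becomes a candidate
through `hairpin_candidate()` and `criteria_check()`:

* **(a) one arm, no large loops** — the mature span must lie entirely 5'
  or 3' of the terminal loop of *its own* stem (the nearest hairpin loop
  in the MFE structure; judging against all loops in the 100-nt window
  would let small independent folds in the flanks obscure a clean
  placement), and may contain no unpaired run longer than
  `max_unpaired_run = 4` nt. "Large internal loops or bulges" comes with
  no published number; 4 nt is the package's quantification and is
  configurable.
* **(b) steady fold** — MFE strictly below −20 kcal/mol ("lower than"
  reads as strict inequality).
* **(c) location** — the locus overlaps an intergenic region or an
  intron; anything touching an exon or rRNA fails. Window extraction
  (`extract_window()`) centres 100 nt on the mapped tag, truncates at
  contig ends, and reverse-complements minus-strand loci.

Catalog matching is exact sequence identity by default (T/U-insensitive)
with lexicographic tie-breaking; a `max_mismatch` knob allows Hamming
matching. Inventory overlap between libraries is plain set arithmetic.

## Differential expression

For miRNAs, the altered rule: evaluable only with at least 10 copies in
both libraries; then a two-fold copy-number difference in either
direction is called up/down, anything smaller equal. Raw copies are
compared by default because the decision rule is stated in copy
numbers; a per-million flag exists because library sizes differ.

For genes, RPKM = 10⁹·C/(N·L) and the log₂ RPKM ratio; genes with zero
counts in both samples are excluded, and a single zero receives a
0.5-count pseudo-offset *only* for the reported ratio — the test always
uses the raw integers. The equal-expression probability is the
Audic–Claverie conditional model: given x reads at depth N₁, the count y
at depth N₂ under equal expression follows

p(y|x) = (N₂/N₁)ʸ (x+y)! / ( x! y! (1+N₂/N₁)^(x+y+1) ),

which is exactly a negative binomial with size x+1 and success
probability N₁/(N₁+N₂); tails are accumulated through `pnbinom` (log
space internally) and verified in the tests against direct log-space
summation of the terms. The two-sided p-value doubles the smaller of the
two *directional depletion* tails, P(Y ≤ y | x) and P(X ≤ x | y), each
taken from the conditional model in its own direction, capped at 1. We
chose this construction over the textbook "double the smaller tail of
one conditional" because the latter is not symmetric under exchanging
(x, N₁) with (y, N₂) — the conditional privileges its conditioning
count — whereas a symmetric statistic is clearly the right property for
a two-sample comparison with no distinguished sample. The chosen form is
symmetric by construction and agrees with direct tail summation on
one-sided extremes. N₁ and N₂ default to total clean reads (the totals
the formula names), not mapped reads; callers can pass either.

FDR is Benjamini–Hochberg (`p.adjust`; the tests check it against a
hand-written step-up), and a gene is called at FDR < 0.001 and
|log₂ ratio| > 1.

**Assumption to keep in view:** the Audic–Claverie statistic models
Poisson sampling of one pooled library per condition. Under the count
generator's default overdispersion (0.05) it is anti-conservative — the
workflow drivers demonstrate a few percent of null genes called at the
paper-style thresholds — which is a property of the single-pooled-sample
design itself, not of the implementation. The calibrated guarantees
(null p-values uniform with Kolmogorov–Smirnov distance < 0.05 at 5,000
genes; at most 0.2% of null genes called) are therefore asserted under
Poisson sampling (`dispersion = 0`), which is exactly why the generator
exposes that degenerate setting, while power (≥ 90% recovery of planted
|log₂ fold| = 3 genes at high counts) is demonstrated with
overdispersion on.

## Target prediction

`duplex_mfe()` minimises the intermolecular duplex energy between a
miRNA and a target window under the same energy model, with
intramolecular pairing forbidden: a monotone antiparallel matching whose
gap-free steps are stacks, one-sided gaps bulges and two-sided gaps
internal loops; the empty duplex scores 0. The C++ DP is quadratic in
the product of lengths and is verified against exhaustive matching
enumeration on 200 random pairs. `predict_targets()` scans transcripts
in 60-nt windows with a 30-nt step (bounded to keep the DP desk-scale;
both configurable), reports the single lowest-energy site below the
cutoff with ties broken by leftmost position, and can optionally require
contiguous pairing of the seed region (miRNA positions 2–8) — off by
default, since the original ranking was pure MFE. The default cutoff of
−20 kcal/mol mirrors the hairpin threshold; no published target cutoff
exists.

A caution the package measures rather than hides: at the −20 cutoff a
random 22-mer is called a "target" of a substantial fraction of random
transcripts (the best of many windows crosses the threshold by chance,
the more often the longer the transcript). Low specificity is intrinsic
to pure-MFE target scanning — the original study itself notes single
miRNAs targeting over a thousand genes — so downstream overlap
statistics (`overlap_report()`) should be read as descriptive
arithmetic, not as evidence of regulation. The tested guarantees are
oracle equivalence, recovery of planted perfect sites (with the most
negative energies in the map), leftmost tie-breaking, and monotonicity
of the target count in the cutoff.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not sequencing chemistry:

* **Genome** (`make_genome()`): one contig of uniform random sequence
  with non-overlapping genes (exons separated by introns), rRNA features
  and explicit intergenic gaps; hairpin precursors (perfect stems with a
  G/C clamp and an unpaired A-loop, mature strand verbatim on the 5'
  arm) are overwritten into intergenic, intronic, or — for negative
  controls — exonic hosts. Infeasible packings raise a sizing error.
* **Small-RNA libraries** (`simulate_srna_library()`): reads are drawn
  from a nine-class mix whose default follows the rates observed in a
  deep royal-jelly library — a fraction of a percent lost to quality and
  adapter failures, roughly 12% of inserts below 18 nt, and the clean
  remainder dominated by rRNA fragments and degradation products with a
  small mature-miRNA fraction. Clean-class inserts are genuine genomic
  subsequences followed by the 3' adapter and random fill; contaminant
  classes reproduce the cleaning failure modes exactly. Adapters are
  arbitrary fixed 12-mers (configurable); reads are emitted on the
  forward strand only (mapping still searches both); quality strings are
  flat Phred 40 except for the low-quality class (Phred 2) — no realistic
  base-call error model, by design.
* **Counts** (`simulate_counts()`): negative binomial around per-gene
  baseline means (log-normal around several hundred reads, the scale of
  a deeply sequenced library of ~10⁷ clean reads), sample 2 scaled by
  2^(log₂ fold) and by the depth ratio; dispersion 0 degenerates to
  Poisson. Lengths default to 500–3,000 nt.
* **Target sites** (`plant_target_sites()`): the reverse complement of a
  mature miRNA (or of its seed only) embedded near the 3' end of a
  gene's last exon, so planted sites survive into the spliced
  transcript.

Every generator is deterministic given its seed (`withr::with_seed`, so
the caller's RNG state is untouched) and emits a truth table in which
every read, count and site appears exactly once. What passing tests on
these data show is that the *computations* are correct and calibrated
under the stated models; they cannot show robustness to adapter
sequencing errors, strand bias, expression-dependent degradation or
other properties of real libraries that the generator deliberately
omits.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use sizes chosen to exercise
every code path at desk scale: 500 random sequences (≤ 25 nt) for the
folding oracle, 200 pairs (≤ 12 × 15 nt) for the duplex oracle, 24
legally planted and 12 exon-planted hairpins across multiple genomes,
20,000-read libraries for cleaning recovery, 50 kb genomes for the
mapping oracle, and 2,000–5,000-gene count tables for calibration and
power. Energies are exact rational multiples of 0.5 under the default
model, so DP-vs-oracle comparisons are exact to machine precision;
percentage formatting is fixed-point half-up at two decimals (one for
the overlap share), matching the printed tables the reporting functions
reproduce. Degenerate inputs have defined behaviour throughout: empty
FASTQ files yield all-zero summaries, empty reads are insert-null,
all-unpairable sequences fold to the open chain at 0 kcal/mol, and
zero-in-both-samples genes are excluded before testing.
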