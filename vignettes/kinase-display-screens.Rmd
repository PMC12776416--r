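---
title: "Scoring bacterial display kinase-specificity screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring bacterial display kinase-specificity screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdisplay)
```

## The assay and what the package computes

A tyrosine kinase recognizes its substrates partly through the residues
flanking the phospho-acceptor tyrosine. Bacterial display screens measure
this preference at scale: a genetically encoded peptide library is displayed
on the *E. coli* surface, phosphorylated by a purified kinase domain, the
phosphorylated cells are pulled down with a biotinylated pan-phosphotyrosine
antibody on avidin beads, and both the enriched (**sorted**) and input
(**unsorted**) populations are deep-sequenced. Relative phosphorylation
efficiency is then read out as the ratio of a peptide's frequency between
the two samples.

`pepdisplay` implements everything downstream of the sequencer, plus the
library design and bench-planning arithmetic upstream of it, plus a
simulator that makes the whole pipeline testable against a known ground
truth.

## Library architectures and oligo design

All libraries share one coding cassette flanked by constant DNA
(`GCTGGCCAGTCTGGCCAG` ... `GGAGGGCAGTCTGGGCAGTCTG`); the flanks drive both
cloning and read extraction. Three architectures are supported:

* **defined** — an explicit peptide list, reverse-translated with a fixed
  per-amino-acid codon table. We use, for each amino acid, the most frequent
  *E. coli* codon whose third base is G or C, so defined members live in the
  same codon space as NNS-degenerate libraries; explicit codons can be
  supplied per member when a specific printed sequence must be reproduced.
* **degenerate (X5-Y-X5)** — `NNS` codons at ten positions around a fixed
  central tyrosine (codon `tat`). `NNS` (third base G/C) encodes all 20
  amino acids plus the amber stop `TAG`, and excludes the hard terminators
  `TAA`/`TGA`. Canonical diversity is 20^10, or 21^10 when the amber
  position is read through as a non-canonical amino acid.
* **scanning** — one template per position of a reference peptide, with
  `NNS` at that position and the reference codons elsewhere. Each cassette
  therefore encodes the reference residue, the 19 substitutions, and an
  amber variant (`theoretical_diversity()` counts 19 L + 1 canonical
  peptides, plus L amber variants).

`validate_oligo()` checks flank presence, frame, and pattern conformity;
templates are emitted with uppercase flanks and a lowercase coding region,
matching the conventional typography of printed pools.

## Read processing

`process_sample()` converts paired FASTQ into translated peptide records in
three stages, each with explicit failure accounting (`merge_fail`,
`flank_fail`, `frame_fail`, `length_fail`, `terminator_fail`; the status
counts always sum to the number of input pairs):

1. **Merge.** The reverse read is reverse-complemented and the best
   suffix–prefix overlap is chosen by the score *matches − mismatches*,
   subject to a minimum overlap (default 10 nt) and a maximum mismatch
   fraction (default 0.25); ties go to the longer overlap. At mismatched
   overlap positions the higher-quality base wins. A bulk fast path handles
   the common exact-overlap case; ambiguous pairs fall back to the full
   scalar search.
2. **Extract.** The insert is the substring strictly between the constant
   36-nt 5′ anchor and 37-nt 3′ anchor of the amplicon (the leftmost 5′
   match, then the nearest 3′ match). Each anchor tolerates one substitution
   by default: the protocol specifies no tolerance, and at these anchor
   lengths a single allowed mismatch absorbs typical sequencing error with
   no realistic risk of off-target matches. Only substitutions are
   tolerated, not indels. If both anchors are missing, the
   reverse-complement orientation is tried and recorded.
3. **Translate.** Frame starts at base 1. `TAG` translates to `*` — a
   candidate non-canonical residue under amber suppression. `TAA`/`TGA`
   cannot encode displayed peptide, so such reads are rejected by default
   (`terminator_fail`); a diagnostic mode maps them to `X` instead. No base
   quality filter is applied by default, again following the protocol.

Degenerate-library positions are displayed as −5 … +5 with the central
tyrosine at 0; internally, matrices are indexed 1 … L.

## The three scoring schemes

All schemes share the same core: counts → frequencies within each sample →
sorted/unsorted ratio, always against the *matched* unsorted sample.
Replicate averaging (mean of log scores) is a separate, explicit post-step,
never implicit.

**Discrete.** Per-peptide frequency ratios, with log2 and log10 transforms.
Zeros in the unsorted sample are flagged `undefined` rather than reported as
infinite; an optional additive pseudocount (0.5 when enabled) is applied to
both samples symmetrically, since the assay itself defines no zero policy.
`select_for_logo()` reproduces the conventional logo input: foreground =
single-tyrosine peptides with enrichment above the cutoff (default 3),
background = all single-tyrosine peptides.

**Position-specific (degenerate).** Individual peptides in a 20^10 library
are essentially unique, so scoring aggregates to a 21 × L count matrix (20
amino acids plus the amber row `*`, ordered with `*` last so serialized
output is byte-stable). Column sums give per-position totals; cells become
within-column frequencies; the sorted/unsorted ratio is log-transformed for
display (log2 is the customary scale here). The central fixed column is
masked (`NA`): the design encodes almost nothing but tyrosine there, so
ratios in that column are meaningless.

**Scanning.** The point-mutant matrix writes the wild-type count into the
reference-residue cell of *every* column, so the raw matrix sum overcounts
the wild type L − 1 times. Sample totals therefore use
`sum(matrix) − wt_count × (L − 1)` — the multiplier is 10 for an 11-mer —
which equals the true number of contributing reads. After the ratio and log
transform (log10 customary), the reference's log score is subtracted, so
the reference is exactly 0 everywhere, mutations that hurt phosphorylation
are negative, and stop mutations at the central tyrosine serve as the
internal negative control. Peptides differing from the reference at two or
more positions are excluded and reported, and peptides equal to the
reference through synonymous codons count as wild type: counting is at the
peptide level, after translation.

**Amber (one-stop) mode.** Under amber suppression, sequences without an
internal amber codon express more efficiently than amber-containing ones,
which would make every amber-containing peptide look depleted regardless of
its quality as a substrate. The `onestop` filter therefore restricts both
samples to peptides with *exactly one* amber codon before building the
position matrices; the `*` row of the resulting enrichment matrix reports
the non-canonical residue's positional preference. Records with two or more
ambers are excluded outright, not truncated. The `nostop` and `full`
filters complete the conventional trio.

## The simulator: what it emulates and what it does not

The simulator exists so that every downstream stage can be validated against
a known ground truth with no external data. Its components:

* **Specificity model.** A 21 × L matrix of log-preferences plus a baseline
  rate. Phosphorylation follows first-order reaction-extent kinetics:
  `p = 1 − exp(−rate × time × exp(Σ weights))`, monotone in every weight.
  `calibrate_exposure()` root-finds the exposure at which the
  population-mean extent hits a target — default 0.375, the midpoint of the
  25–50% window that practitioners target when tuning reaction conditions.
* **Population sampling.** Defined pools draw cells multinomially across
  members; degenerate libraries draw NNS codons uniformly per position (so
  amino acid frequencies carry the natural NNS bias, and amber appears at
  1/32 per position); scanning libraries draw from the reference plus all
  single mutants. An optional log-normal abundance skew models uneven
  cloning representation.
* **Selection.** Per cell: Bernoulli phosphorylation at the peptide's `p`,
  then Bernoulli capture at 0.9 if phosphorylated, 0.01 otherwise. These
  capture numbers are plumbing defaults for testing — the assay provides no
  quantitative estimates of bead capture or background, and they must not
  be read as biological parameters. Selection is single-round with no
  amplification bias.
* **Read emission.** Reads are drawn multinomially from the population;
  each amplicon gets fresh random 6-mers at its N positions, the constant
  flanks, and coding sequence from the design's codon policy; 75 + 75 nt
  pairs (matching a 150-cycle paired-end kit) cover the 118-nt 11-mer
  amplicon with a 32-nt overlap. Sequencing errors are substitutions only,
  consistent with extraction's substitution-only tolerance. A truth table
  of the sampled read counts accompanies every FASTQ pair, and identical
  configurations produce byte-identical output.

What the simulator does **not** model: antibody and bead binding kinetics,
bead saturation, PCR amplification bias (exposed only as an optional
abundance-skew hook), indels, quality-score structure, and cluster
artifacts. Passing tests therefore demonstrate the correctness of the
computational pipeline under its stated assumptions, not the behavior of
the wet assay on real data.

## Numerical conventions and edge cases

* Ratios with a zero denominator are `NA` + flagged, never `Inf`; the
  pseudocount (when enabled) is added to both samples.
* The merge scorer breaks ties toward the longer overlap; at equal
  qualities the forward base wins a mismatch.
* Matrices use a fixed residue order with `*` last; serialized TSVs carry a
  one-line provenance header.
* `calibrate_exposure()` brackets the root by doubling and solves to a
  relative tolerance of 1e−10, then verifies the achieved extent within
  0.5% absolute.
* Zero corrected totals, empty count tables, shape or filter-mode
  mismatches, and unmatched sorted samples are hard errors raised before
  any partial output is written.
* All randomness flows from explicit integer seeds; RNG state is restored
  after every simulator call.

## Problem sizes used in validation

The bundled validation runs at desk scale, chosen to exercise every code
path with comfortable statistical margins: end-to-end FASTQ round trips use
20,000 read pairs at zero error rate (recovery must be exact), and
position-weight recovery uses a 200,000-read, 200,000-cell degenerate
screen, where the Pearson correlation between ground-truth weights and
recovered log2 enrichments exceeds 0.9 (0.94 at the default seed). The
amber scenario plants a 3× non-canonical preference at +1 and requires the
`*` row to recover its sign and rank. Fixture scenarios
(`make_fixtures()`) scale these down further for fast unit testing.

## Planning arithmetic

The planner reproduces the protocol's bench numbers: molarity conversion at
660 g·mol⁻¹·bp⁻¹ (no GC correction), serial dilutions as products of
carried/(carried + added), sequencing depth as library size × reads per
variant (200–500 reads per sequence is the working range; 10,000 sequences
at 200 reads → 2 million reads per sample, 10–15 samples on a 20–30
million-read kit, floor division), and the loading mix as the closed-form
solution of the molarity/volume/spike-share constraints.

## Known limitations

* Flank matching tolerates substitutions only; an indel inside an anchor
  loses the read.
* Whitelist matching for defined libraries is exact; no fuzzy rescue of
  near-miss peptides.
* Amplicon-length bookkeeping is validated against flank-plus-coding
  arithmetic only; full vector-context amplicon lengths depend on vector
  sequence outside the package's scope.
* The enrichment/kinetics relationship is reported on both linear and log
  scales; choosing between them for downstream modeling is left to the
  analyst.
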