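---
title: "Models and methods behind pirnaforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pirnaforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological model

*C. elegans* piRNAs (21U-RNAs) are 21-nt small RNAs with a 5′ uracil, bound
by the Piwi Argonaute PRG-1. Most derive from individual transcription
units marked by the **Ruby motif**, an 8-nt core consensus `CTGTTTCA`
located roughly 40 bp upstream of the mature 5′ U and separated from it by
an A/T-rich spacer; a minority of loci lack the motif. Each locus is
transcribed by RNA Pol II into a short **capped precursor** that begins
2 nt upstream of the mature 5′ U and peaks at 28–29 nt in length, which is
then processed into the mature 21-mer. Genotypes dissociate the stages:
loss of *prg-1* removes mature piRNAs (both classes) but leaves precursors
intact; loss of *prde-1* removes both precursors and mature piRNAs — but
only for motif-dependent loci, while motif-independent piRNAs persist at
slightly elevated levels. Mature piRNAs direct the synthesis of antisense
secondary siRNAs (**22G-RNAs**: ~22 nt, 5′ G, made by RdRPs) on target
transcripts, so loss of a piRNA class de-silences its targets, which is
visible both as loss of per-gene antisense 22G-RNAs and as up-regulation in
expression profiling.

`pirnaforge` implements this chain as testable operations: motif scoring
and two-class locus classification, exact-match read assignment with
precursor calling from the 5′-extension/length geometry, genotype-wise
depletion statistics, and the downstream 22G/expression analysis — plus a
synthetic-data generator that emulates the whole design with a ground
truth, so every claim the pipeline makes can be scored for recovery.

## Motif model

The score of a locus is the maximal log2-odds of an 8-position PWM over a
window of *offsets*, where the offset is the distance from the core's 3′
end to the mature 5′ base. Choices that needed fixing, and why:

- **Window 30–50 bp.** The motif sits "about" 40 bp upstream; ±10 bp
  absorbs the spacer-length variability without letting the scan wander
  into unrelated sequence. Ties between equally scoring placements break
  toward offset 40, then toward the smaller offset, so reported offsets
  are deterministic.
- **Units: bits (log2), uniform background, pseudocount 1.** A unit had to
  be chosen; in bits the planted-core and background modes separate
  cleanly and the classical cutoff of 7 falls between them (the score
  histogram of a wild-type locus set is bimodal, with the independent
  class modal far below zero). A consensus-only alignment with vanishing
  pseudocount scores 8·log2(4) = 16 bits at the consensus.
- **Classification is strict:** score > 7 is motif-dependent, score ≤ 7
  (including exactly 7) motif-independent.
- **Training.** `train_pwm()` scans each locus's window for the placement
  closest to the known core consensus and builds the matrix from aligned
  instances within one mismatch, leaving non-motif loci out of the
  alignment — the matrix is weighted by the upstream regions of the
  high-confidence subset. `extract_upstream_cores()` offers the simpler
  fixed-offset extraction for training on a trusted locus list, and
  `build_pwm()` accepts any externally supplied alignment, so a matrix from
  other sources can be dropped in. Only the 8-mer core is scored; spacer
  and flank positions are not part of the matrix.

## Precursor calling

Reads are assigned to loci by **exact match only** against locus-anchored
windows (10 nt upstream of the mature 5′ base to 20 nt past the mature 3′
end). No aligner and no mismatch tolerance: the species definitions are
geometric, and exact matching keeps every result bit-reproducible. A read
must cover the mature 5′ base with its 5′ end at or upstream of it;
`five_prime_ext` is then strand-uniform because a locus is stored by the
genomic coordinate of its 5′ base (the BED interval end − 1 on the minus
strand). Calls:

- `mature`: no 5′ extension, length equal to the annotated mature length;
- `precursor_candidate`: longer than the mature species (the 2-nt 5′
  extension is a *result* read off the profile, not an input assumption);
- `other_locus_overlap`: covers the 5′ base but is shorter than mature, or
  trips the guards (5′ extension > 10 nt, length > 45 nt) that keep
  degradation fragments out of the profiles — observed precursors are
  almost never longer than 36 nt, so the guard costs nothing;
- `unassigned`: no exact match at any locus.

Reads matching several loci are counted once in global profiles (the
`primary` row: smallest 5′ extension, then lexicographic locus id) and once
per locus in per-locus tables, flagged `multi` — double counting would
distort global modes, while per-locus tables should not silently drop
signal. Modal values always break ties toward the smaller value. The
untreated / TAP / capRNA protocols are compared by mature and precursor
fractions: 5′-monophosphate-dependent cloning cannot see capped species,
TAP (decapping) reveals them, and the cap-selected nuclear protocol
contains only them.

## Abundance statistics

Counts are normalized to **reads per million of the total library** (not of
the assigned subset), so assigned RPM sums to 1e6 times the assigned
fraction. Depletion is tested with a **one-sided paired Wilcoxon
signed-rank** test: loci are natural pairs across genotypes, and pairing is
strictly more powerful than the rank-sum alternative (available via
`paired = FALSE`). Exact p-values are used for n ≤ 25, the normal
approximation with continuity correction beyond; all-zero difference
vectors return p = 1 with a warning. Fold changes are reported with a
0.1-RPM pseudocount (division only; ranks are computed on raw values).

## Target and expression analysis

- **Target search**: the reverse complement of the piRNA is slid along each
  transcript and every ungapped window within three mismatches (plain
  Hamming distance, no G:U wobble) is a hit. The implementation uses
  Biostrings pattern matching; the test suite checks it against an
  exhaustive all-window enumeration written independently.
- **22G quantification**: reads of 20–23 nt with a 5′ G (a strict 22-only
  switch exists) matching the genome exactly in antisense orientation
  within a gene body, RPM-normalized; a per-position 5′-start profile is
  available per gene.
- **DE gene sets**: per mutant-vs-wild-type contrast, mean log2 fold
  change, **Welch** t-test (safer than pooled variance at a handful of
  replicates; a pooled-variance flag exists), and **Benjamini–Hochberg**
  q-values across genes (the correction method had to be chosen; BH is the
  field default). A gene passes at log2FC **strictly** above log2(4),
  p < 0.05 and q < 0.1; sets are `shared` (prg-1 and every prde-1 allele),
  `prg1_only`, `prde1_only`. The p gate is per contrast, with BH applied
  within each contrast.
- **Enrichment**: Fisher's exact test on the 2×2 hit table (sample odds
  ratio reported; zero-margin tables give p = 1 and an undefined odds
  ratio) and a permutation gene-set test whose statistic is the mean
  per-gene score of the set against same-size random sets, with the
  add-one p estimator. Two score distributions are compared with the
  two-sided Mann–Whitney test with tie correction.

## The synthetic-data generator

`sim_config()` defaults *are* the emulated study conditions: two 200-kb
chromosomes (a piRNA-cluster chromosome and a gene chromosome), 300
motif-dependent and 60 motif-independent loci, core offsets drawn from
38–42 bp with the mode at 40, spacers 75% A/T, precursors starting exactly
2 nt upstream with lengths on 26–36 nt and the mode shared between 28 and
29, library depth 200,000, 5% degradation background (random genomic
slices of 15–35 nt), and genotype multipliers: *prg-1* zeroes mature
species and keeps precursors; *prde-1* zeroes motif-dependent mature and
precursor species, keeps motif-independent precursors and raises
motif-independent mature piRNAs ×1.25 ("slightly increased" is not
quantified anywhere, so the uplift is a config default, not a claim).
Choices worth explaining:

- **Precursor 3′ ends.** Only the 5′ end (+2 nt) is structurally fixed;
  drawing the *total* length from the 26–36 distribution reproduces the
  observed 28–29 nt mode without asserting an unobserved 3′-end rule.
- **"Almost completely absent" is modeled as multiplier 0.** The residual
  reads seen in depleted libraries lack the 2-nt signature, i.e. they are
  background — which the generator's background fraction supplies
  naturally, rather than a small positive rate at the silenced loci.
- **Locus abundances** are drawn once (log-normal, σlog = 1) at genome
  generation and shared by all libraries, so loci are genuinely paired
  across genotypes, as the paired Wilcoxon assumes.
- **22G reads** are 22-nt antisense slices whose start positions are chosen
  where the genomic context yields a 5′ G, so every simulated read is an
  exact antisense genome match. Shared targets lose 22Gs (×0.1) in both
  mutants, prg-1-only targets in *prg-1* only; prg-1-only targets get a
  lower wild-type baseline (×0.6), mirroring the observation that they
  carry fewer 22G reads to begin with.
- **Expression** adds +2.5 log2 (Gaussian noise σ = 0.4) exactly in the
  genotypes where a gene's 22Gs are lost. The default of **5 replicates
  per genotype** is a power calculation, fixed before any testing: the
  binding gate is the strict fourfold fold-change threshold, and detecting
  a +2.5 log2 effect through a >2.0 estimated-log2FC gate at σ = 0.4 needs
  ~5 replicates for >95% per-contrast power (the shared set requires two
  contrasts to pass jointly).
- A subset of gene bodies (70% of targets, 30% of untargeted genes)
  carries a planted antisense piRNA site with 0–3 substitutions, so the
  target-search and Fisher-enrichment stages have real signal to find.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: sequencing errors and PCR duplication
(matching is exact; real pipelines must handle mismatches from errors),
non-uniform genomic base composition and repeats (multi-mapping is far
rarer here than in a real genome), partial genotype penetrance, 5′-U bias
violations (mature species are always 5′ U by construction), and chemical
cap validation (the capped flag is truth-side bookkeeping, not chemistry).

## Problem sizes and determinism

All randomness flows from one top-level seed through fixed per-stage
substreams, so any stage can be rerun in isolation and full reruns are
byte-identical. The shipped test suite runs the generator at its default
size (200-kb chromosomes, 200,000-read libraries) for the end-to-end
recovery checks and at a 40-kb / 20,000-read configuration for unit tests
and the brute-force oracle comparisons; the oracle implementations
(all-position exact matching, all-window target enumeration) are kept in
the test helpers, independent of the package code paths they check.

## Known limitations

- Exact matching cannot assign reads from loci overlapping `N` bases or
  reads carrying sequencing errors; such reads are `unassigned`.
- The PWM models the 8-mer core only; if the operative motif includes
  informative spacer or flank positions, scores will understate the true
  separation (an externally trained matrix can be supplied).
- The two-class cutoff of 7 bits is taken as given, not re-estimated from
  the bimodal histogram.
- `find_targets` is quadratic in (piRNAs × transcript length) and meant
  for curated transcript sets, not transcriptome-scale scans.
- The permutation set test assumes exchangeable genes under the null; it
  does not model gene–gene correlation.
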