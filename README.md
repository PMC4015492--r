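# pirnaforge

Small-RNA informatics for *Caenorhabditis elegans* piRNA (21U-RNA)
biogenesis. The package implements, as reusable and tested R functions, the
analysis chain used to dissect how mature piRNAs arise from short capped
precursors and what happens to them in biogenesis mutants:

- **Ruby-motif scoring** — a position weight matrix over the 8-nt core
  consensus `CTGTTTCA` found ~40 bp upstream of the mature 5′ U. Loci are
  scored as the maximal log2-odds placement over a 30–50 bp offset window
  and split at a cutoff of 7 bits into *motif-dependent* (score > 7) and
  *motif-independent* (score ≤ 7) classes.
- **Precursor calling** — exact-match assignment of library reads to
  annotated loci, with species calls from the 5′-extension/length geometry:
  a mature 21U-RNA has no 5′ extension and is 21 nt; a capped precursor
  candidate starts 2 nt upstream of the mature 5′ U and peaks at 28–29 nt.
  Cloning-protocol semantics (untreated / TAP-treated / cap-selected
  nuclear RNA) are modeled explicitly.
- **Depletion statistics** — per-locus RPM tables across genotypes and
  one-sided Wilcoxon signed-rank tests for class-wise reduction
  (e.g. *prde-1* loses only the motif-dependent class; *prg-1* loses mature
  piRNAs of both classes but keeps precursors).
- **Target analysis** — antisense piRNA target search with up to three
  mismatches, per-gene antisense 22G-RNA quantification (20–23 nt, 5′ G,
  RPM-normalized), fourfold/p/q differential-expression gene sets, Fisher
  enrichment and permutation gene-set tests.
- **Synthetic data** — a seed-controlled generator that emulates the study
  design (wild-type, *prg-1*, *prde-1* libraries under all three cloning
  protocols, 22G libraries and a matched expression matrix) together with a
  ground-truth set, so every stage can be scored for recovery.

## Worked example

```r
library(pirnaforge)

sim <- generate_genome(sim_config(seed = 7))          # 360 loci on a 200 kb cluster
tap <- generate_library(sim, "wild_type", "TAP")       # 200,000 reads
al  <- assign_reads(tap$library, sim$genome, sim$loci)
extension_profile(al, "precursor_candidate")
#> extension_profile wild_type_TAP (wild_type/TAP): 24,710 reads; modal ext 2 nt, modal length 28 nt

pwm    <- train_pwm(sim$genome, sim$loci)              # aligned-core PWM
scored <- score_loci(sim$genome, sim$loci, pwm)        # adds score + class
table(scored$class_label, sim$truth$loci$true_class)
#>                     motif_dependent motif_independent
#>   motif_dependent               300                 1
#>   motif_independent               0                59
```

The modal 2-nt 5′ extension and 28-nt length are the capped-precursor
signature; the confusion table shows two-class recovery at the 7-bit
cutoff (errors are loci whose random upstream background happens to score
above it). `pirna_demo(out_dir, seed = 7)` runs every stage end to end and
writes all tabular artifacts plus a provenance block;
`inst/scripts/pirna-forge` exposes the same stages as shell subcommands.

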