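---
title: "Quantifying promoter-driven bias in cosmid metagenomic libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying promoter-driven bias in cosmid metagenomic libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cosmidbias)
```

## The problem

Large-insert clone libraries (cosmids, fosmids) are a standard way to
capture long contiguous stretches of metagenomic DNA in a culturable
host, almost always *E. coli*. Such libraries are known to be
compositionally biased: AT-rich taxa that dominate the source DNA can be
nearly absent from the final library. `cosmidbias` implements an
analysis chain for attributing that bias to a specific mechanism —
constitutive transcription initiated from sigma-70 (*rpoD*) consensus
promoters that happen to sit on cloned inserts, destabilizing the clone
— and a generative simulator of the library-construction workflow on
which the whole chain can be exercised end to end with known ground
truth.

The package deliberately separates three questions that are conflated
in a raw GC comparison:

1. Does fragmentation or size selection itself distort composition?
   (In both the data this models and the simulator's null: no.)
2. How many sigma-factor consensus promoters does a sequence carry, and
   how many would it carry *by chance* given its GC content?
3. Does per-taxon library bias track genome GC, or the genome's *rpoD*
   consensus density, once the two are decoupled?

## Motif model and match semantics

A sigma-factor consensus is modeled as ordered conserved blocks
separated by bounded variable-length spacers. The five built-in motifs
are the *E. coli* housekeeping consensus and four controls:

```{r}
for (m in builtin_motifs()) print(m)
```

*rpoN* has a GC-rich consensus and sigABfr (the *Bacteroides* primary
sigma factor) is not recognized by *E. coli*; neither should respond to
an *E. coli*-specific loss mechanism, which is what makes them useful
controls alongside *rpoE* and *rpoH*.

Match semantics are fixed and documented because they change counts:
scanning is leftmost and non-overlapping, and a spacer is extended
greedily — one hit per admissible start, reported at the longest spacer
that completes the match, with scanning resuming after the hit's end.
These are exactly the semantics of greedy bounded repetition in a
backtracking regular-expression engine, which is also how the scan is
executed. Overlapping counting would give systematically higher counts;
with non-overlap the maximum undercount is bounded by the rarity of
adjacent sites. A conserved position never matches N; spacer positions
match anything, N included. Both strands are scanned by default: a
promoter is strand-specific, but the orientation of an insert relative
to the vector is random, so either orientation can fire in vivo.
Coordinates are 0-based and half-open throughout.

The test suite holds the scanner to an independent brute-force oracle
(exhaustive enumeration of every start and spacer vector, applying the
same leftmost/greedy/non-overlap rule) across random sequences at 30,
50 and 70% GC, all five motifs, both strands.

## The chance-promoter background

Under an i.i.d. base model with P(A) = P(T) = (1 − gc)/2 and
P(G) = P(C) = gc/2, the expected hit density is

```{r}
expected_hits_per_mb(builtin_motifs()$rpoD, 0.5)   # per Mb, both strands
expected_hits_per_mb(builtin_motifs()$rpoD, 0.3) /
  expected_hits_per_mb(builtin_motifs()$rpoD, 0.7)
```

i.e. the number of admissible spacer-length combinations times the
product of per-position set probabilities, per position scanned,
ignoring overlap corrections (valid in the rare-motif regime). Ten of
the twelve conserved *rpoD* positions are A/T, so a 30%-GC genome
carries several hundred times more chance *rpoD*-consensus sites than a
70%-GC genome. This is the quantitative form of the argument that GC
content may be a mere proxy: AT-richness inflates promoter-like content
by chance alone, and the mechanistically relevant variable is the
promoter density itself.

## The simulator

`run_experiment()` is a generative stand-in for the wet-lab workflow:
community genomes → crude extract → size selection → cloning →
paired-end sequencing of all three stages, with truth labels.

Parameters and defaults (all in `simulation_params()`):

* **Community**: per genome, a length, a target GC fraction, a planted
  *rpoD* site count and a DNA share. Genomes are i.i.d. bases at the
  target GC with planted sites (consensus blocks, random spacer, random
  strand) overwritten at non-overlapping uniform positions. Planting is
  exact by construction — on an inert background the scanner finds
  every plant — and the genome records its *measured* count, which can
  exceed the planted count through chance hits (on AT-rich genomes it
  does, which is realistic). Fragment sampling weights genomes by their
  DNA share, so the per-genome base share of the crude pool matches the
  community's DNA fractions.
* **Fragmentation**: each crude fragment is sheared debris with
  probability `debris_fraction` (default 0.25; a crude extract shows a
  heavy smear of sub-10-kb material), drawing its length uniformly from
  `debris_length_range` (default 0.5–5 kb), otherwise from
  `hmw_length_range` (default 30–90 kb, straddling the selection
  window); starts are uniform with truncation at genome ends.
* **Size selection**: the closed window 40–70 kb by default, matching
  pulsed-field selection of cloning-ready fragments. (The workflow this
  emulates reports a smaller realized mean insert, ~28 kb, than its
  selection window; both the window and the length distributions are
  configurable for that reason, and the defaults follow the stated
  selection protocol.)
* **Clone loss**: a fragment carrying k *rpoD* consensus sites (both
  strands, cached at extraction) survives cloning with probability
  exp(−λk). The per-promoter independent hazard is the simplest
  monotone form of the transcription-driven instability hypothesis, it
  nests the null (λ = 0), and it makes λ identifiable:
  −log P(survive | k) is linear through the origin in k, which is how
  `fit_retention()` estimates it (weighted least squares over k groups;
  groups with no survivors carry no finite log and are dropped).
  λ defaults to 1 per site; no empirical value exists for it, so
  analyses treat it as the free severity parameter and rely on
  self-consistency (recovery from truth tables) rather than an external
  value.
* **Sequencing**: 90-base paired-end reads, error-free by default so
  that subtraction and scanning tests are exact (substitution noise is
  opt-in), insert size 350 bp, fragments sampled by length, positions
  uniform. Every read carries its source genome as an `origin=` header
  token, the simulator's truth label.

Everything is deterministic under `seed`: rerunning `run_simulate()`
reproduces every FASTQ and truth table byte for byte (the manifest
checksums are compared in the tests).

## Host/vector subtraction

`subtract_reads()` removes a read iff its full sequence occurs exactly
— 100% identity over the whole read, either strand — in a reference
(host genome, cloning-ready vector). This is the strictest reading of a
"conservative" perfect-identity screen: a local aligner at 100%
identity can also remove perfect partial matches, so counts from this
module are a lower bound on what such a screen would remove. Reads
containing N are never removed (N cannot match at 100%), mates are
independent, a read matching several references is attributed to the
first in the given order, and references flagged circular are matched
across the origin junction by extending the reference with its own
first `read_length − 1` bases.

## The bias statistic

Per-genome abundance profiles (percent of reads, from truth labels —
the stand-in for taxonomic classification of real reads, which is out
of scope) are compared between crude extract (CE) and cosmid library
(CL): fold change = CL/CE, reported on a log10 scale. Genomes with zero
abundance in a sample get a sentinel (`CE_0`, with precedence, or
`CL_0`) instead of an undefined fold change; sentinel records are
excluded from correlations — any inclusion rule would require an
arbitrary pseudo-abundance — and their counts are always reported.
`correlate_bias()` reports both Pearson and Spearman correlations of
the log10 fold change against genome GC and against *rpoD* sites per
Mb (genome counts are normalized to genome size because community
members differ in length; the raw count is also exposed).

A back-of-envelope quantity ties bias to opportunity:
`fragments_per_genome(2250000, 28000)` = 80 — a 2.25-Mb genome is
covered by ~80 independent ~28-kb cloning opportunities, so a genome
with tens of consensus promoters offers few promoter-free fragments.

## Study designs used in tests and in `scripts/acceptance.R`

Problem sizes were chosen so each check has adequate statistical power
at desk scale while the whole suite stays quick; they are scaled-down
analogs, not reproductions, of a ~600-Mb-per-sample sequencing study.

* *Fragmentation null* (λ = 0): 10 genomes × 250 kb with GC 35–65%,
  1200 fragments, 25% debris. Size selection changes pooled GC by less
  than three bootstrap standard deviations (fragments resampled with
  their selection labels). With λ = 1 and planted density
  anti-correlated with GC, the library pool's GC shifts upward by
  several points.
* *Promoter-content profile*: 10 genomes × 4 Mb (bacterial-genome
  scale, needed so the rarest control motifs occur at stable chance
  counts in the community), GC 30–60% (gut-like), planted densities
  0–40 per Mb drawn independently of GC, λ = 1, 4000 fragments,
  250,000 read pairs per stage. Library *rpoD* hits/Mb drop ~3-fold
  versus the crude extract; all four control densities change less.
* *Bias correlation*: 20 seeded replicates of a 10 × 250 kb community,
  GC and planted density independent, λ = 1, 600 fragments, 3000 read
  pairs per stage. |Spearman(log10 FC, rpoD/Mb)| exceeds
  |Spearman(log10 FC, GC)| in ≥ 90% of replicates.
* *Rate recovery*: 2500 fragments, λ = 1; `fit_retention()` recovers λ
  within 15%.

## What the simulator does and does not emulate

It emulates: multi-genome communities with controllable GC and promoter
density, debris-contaminated fragmentation, window size selection,
promoter-count-dependent clone loss, and labeled paired-end read
sampling. It does not emulate: sequencing-error profiles, chimeras,
amplification bias, vector read-through, gene-product toxicity, or real
taxonomic structure. Passing tests therefore show that the analysis
chain is correct and self-consistent under the stated generative model
— that the scanner counts what it defines, that the statistics recover
planted effects and rates, and that the null designs produce null
results. They do not show that exp(−λk) is the true in-vivo loss law,
nor calibrate λ; on real data the same chain would additionally depend
on a read classifier, which is deliberately outside this package.

## Numerical and degenerate-input choices

* GC denominators exclude N so debris-quality artifacts cannot distort
  profiles; an all-N input is an error, not a 0.
* Ambiguity codes other than N are collapsed to N at ingestion, keeping
  the scanner's alphabet closed.
* Forward and reverse read files of a pair are treated as separate
  datasets when profiling real files; the simulator emits interleaved
  mates with independent labels.
* `size_select` uses a closed interval; boundary lengths are retained.
* Fragments shorter than the sequencing insert are skipped with a
  warning rather than silently dropped.
* Empty scan results are zero-row tables, never errors; a dataset with
  zero total bases is an error (hits/Mb undefined).
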