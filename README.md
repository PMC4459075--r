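# cosmidbias

Large-insert (cosmid/fosmid) metagenomic libraries systematically lose
AT-rich taxa: organisms that dominate the extracted DNA can be almost
absent from the final library. `cosmidbias` implements, in R, the
analysis chain used to pin that bias on a mechanism — constitutive
transcription from sigma-70 (*rpoD*) consensus promoters on cloned
inserts, which destabilizes clones in the *E. coli* host — together
with a seeded generative simulator of the library-construction workflow
so the whole chain can be validated against known ground truth.

It is aimed at people who build or analyze clone libraries from
environmental/microbiome DNA and want to quantify, per taxon, how much
representation was lost and what predicts the loss.

## What it computes

**Consensus-promoter scanning.** A sigma-factor consensus is conserved
blocks separated by a bounded variable-length spacer, e.g. the sigma-70
consensus `TTGACA N15-19 TATAAT` (−35 hexamer, spacer, −10 Pribnow
box). Five motifs are built in (*rpoD*, and *rpoE*, *rpoH*, *rpoN*,
σ^ABfr as controls). Matching is leftmost, non-overlapping, with greedy
spacer extension, on both strands; counts are normalized to hits per Mb
scanned. The chance background under an i.i.d. base model is available
in closed form: for a motif with admissible spacer multiplicity S and
position sets B_j,

    E[hits/Mb] = 2 × 10^6 × S × Π_j P(base ∈ B_j),

so at 50% GC the *rpoD* expectation is 2 × 5 × 10^6/4^12 ≈ 0.60/Mb,
and a 30%-GC genome carries ~870× more chance *rpoD*-like sites than a
70%-GC one — AT-richness inflates promoter content by chance alone.

**Host/vector subtraction.** Reads whose full sequence occurs at 100%
identity (either strand, circular references handled across the origin)
in a host-genome or vector reference are removed before any statistic.

**Per-taxon bias.** Fold change in percent abundance between crude
extract (CE) and cosmid library (CL), log10 scale, with `CE_0`/`CL_0`
sentinels for zero-abundance taxa, correlated (Pearson and Spearman)
against genome GC and against genome *rpoD* sites per Mb.

**Library simulation.** Community genomes with planted promoter
densities → fragmentation (with sheared debris) → 40–70 kb size
selection → cloning, where a fragment with k *rpoD* sites survives with
probability exp(−λk) → 90-bp paired-end reads with truth labels.
`fit_retention()` recovers λ from the truth tables.

## Worked example

A three-genome community where promoter density falls as GC rises, put
through the full workflow at λ = 1:

```r
library(cosmidbias)
set.seed(42)
spec <- community_spec(
  genome_id = c("at_rich", "balanced", "gc_rich"),
  length    = 300000L,
  gc        = c(0.35, 0.50, 0.65),
  planted_rpoD = c(12L, 4L, 0L),
  relative_abundance = c(0.5, 0.3, 0.2))
params <- simulation_params(spec, n_fragments = 800,
                            reads_per_sample = 5000,
                            retention_rate = 1, seed = 42)
ex <- run_experiment(params)
bias <- compute_bias(
  abundance_from_labels(ex$reads$crude_extract, "CE"),
  abundance_from_labels(ex$reads$cosmid_library, "CL"))
print(bias, digits = 3)
#>   genome_id abundance_CE abundance_CL fold_change log10_fold_change sentinel
#> 1   at_rich         50.6         28.7       0.567           -0.2465     none
#> 2  balanced         30.1         32.6       1.084            0.0349     none
#> 3   gc_rich         19.3         38.7       2.003            0.3017     none
```

The AT-rich, promoter-dense genome drops from 50.6% of crude-extract
reads to 28.7% of library reads (fold change 0.57), while the
promoter-free GC-rich genome doubles its share — the library is biased
even though nothing about GC itself was simulated, only promoter
counts. The genome profiles and correlation report make the
attribution explicit:

```r
profiles <- genome_profile(ex$community)
correlate_bias(bias, profiles)
#> <bias_correlation>  log10 fold change (CL/CE) vs genome features
#>   genomes used: 3 (excluded: CE_0 = 0, CL_0 = 0)
#>   gc           pearson   r = +1.000
#>   rpoD_per_mb  pearson   r = -0.979
#>   gc           spearman  r = +1.000
#>   rpoD_per_mb  spearman  r = -1.000
fit_retention(ex$truth$fragment_table)
#> <retention_fit>  per-site clone-loss rate
#>   lambda = 1.0582  (n = 305 fragments, k groups: 0,1,2,3,4,5,6)
```

(In this deliberately confounded 3-genome design GC and density predict
equally; the test suite decouples them over larger communities, where
promoter density wins.) The per-site loss rate used in the simulation
(λ = 1) is recovered as 1.06 from 305 fragment outcomes. Finally, the
coverage arithmetic for a concrete genome:

```r
fragments_per_genome(2250000, 28000)
#> [1] 80
```

a 2.25-Mb genome is ~80 cloning opportunities at a ~28-kb mean insert,
so a few dozen consensus promoters leave few promoter-free fragments.

File-level commands (`run_simulate`, `run_scan`, `run_subtract`,
`run_gc`, `run_bias`) wire the same functions to FASTA/FASTQ/TSV
artifacts; `inst/scripts/cosmidbias-cli.R` exposes them as shell
subcommands. See the vignette in `vignettes/` for the model, match
semantics, parameter defaults and design choices.

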