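# Small community builders shared across simulation tests.

# Ten genomes with GC and planted rpoD density drawn independently;
# GC spans the gut-community range.
independent_community <- function(n_genomes = 10L, genome_length = 250000L,
                                  densities_per_mb = c(0, 8, 16, 24, 32, 40)) {
  gc <- runif(n_genomes, 0.30, 0.60)
  dens <- sample(densities_per_mb, n_genomes, replace = TRUE)
  community_spec(
    genome_id = sprintf("g%02d", seq_len(n_genomes)),
    length = genome_length,
    gc = gc,
    planted_rpoD = as.integer(round(dens * genome_length / 1e6)),
    relative_abundance = 1)
}

# Per-fragment GC, vectorized.
fragment_gc <- function(seqs) {
  af <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs),
                                      baseOnly = TRUE)
  100 * (af[, "C"] + af[, "G"]) / rowSums(af[, c("A", "C", "G", "T")])
}

# Length-weighted pooled GC of a fragment pool from per-fragment GC.
pooled_gc <- function(gc, len) sum(gc * len) / sum(len)

# Bootstrap SD of the difference in pooled GC between a labeled subset
# and the whole pool (resampling fragments, keeping their labels).
boot_gc_diff_sd <- function(gc, len, in_subset, n_boot = 200L) {
  n <- length(gc)
  diffs <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    sub <- i[in_subset[i]]
    if (!length(sub)) return(NA_real_)
    pooled_gc(gc[sub], len[sub]) - pooled_gc(gc[i], len[i])
  }, numeric(1))
  stats::sd(diffs, na.rm = TRUE)
}

# One seeded replicate of the bias-correlation experiment: independent
# GC and planted density, lambda = 1; returns |Spearman| of log10 fold
# change against rpoD density and against GC.
bias_replicate <- function(seed, reads_per_sample = 3000L,
                           n_fragments = 600L) {
  set.seed(seed)
  spec <- independent_community(10L, 250000L)
  params <- simulation_params(spec, n_fragments = n_fragments,
                              debris_fraction = 0.25,
                              hmw_length_range = c(30000L, 90000L),
                              size_select_range = c(40000L, 70000L),
                              retention_rate = 1,
                              reads_per_sample = reads_per_sample,
                              seed = seed)
  ex <- suppressWarnings(run_experiment(params))
  bias <- compute_bias(
    abundance_from_labels(ex$reads$crude_extract),
    abundance_from_labels(ex$reads$cosmid_library))
  corr <- correlate_bias(bias, genome_profile(ex$community))
  sp <- corr$estimates[corr$estimates$method == "spearman", ]
  c(rpod = abs(sp$r[sp$predictor == "rpoD_per_mb"]),
    gc = abs(sp$r[sp$predictor == "gc"]))
}

# The promoter-content experiment: ten genome-scale (4 Mb) community
# members so that even the rarest control motif occurs at a stable
# chance count in the community, lambda = 1, GC and planted density
# independent.
fig5_experiment <- function(seed, reads_per_sample = 250000L,
                            n_fragments = 4000L, lambda = 1) {
  set.seed(seed)
  spec <- independent_community(10L, 4000000L)
  params <- simulation_params(spec, n_fragments = n_fragments,
                              debris_fraction = 0.25,
                              hmw_length_range = c(30000L, 90000L),
                              size_select_range = c(40000L, 70000L),
                              retention_rate = lambda,
                              reads_per_sample = reads_per_sample,
                              seed = seed)
  suppressWarnings(run_experiment(params))
}

# Ten genomes where planted density decreases as GC increases
# (anti-correlated design: AT-rich genomes are promoter-dense).
anticorrelated_community <- function(n_genomes = 10L,
                                     genome_length = 250000L,
                                     max_density_per_mb = 40) {
  gc <- seq(0.35, 0.65, length.out = n_genomes)
  dens <- seq(max_density_per_mb, 0, length.out = n_genomes)
  community_spec(
    genome_id = sprintf("g%02d", seq_len(n_genomes)),
    length = genome_length,
    gc = gc,
    planted_rpoD = as.integer(round(dens * genome_length / 1e6)),
    relative_abundance = 1)
}
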