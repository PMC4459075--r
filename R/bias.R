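# Library-bias statistic: per-genome change in percent abundance between
# the crude extract (CE) and the cosmid library (CL), and its correlation
# with genome GC versus rpoD consensus density.

#' Percent abundance profile from truth-labeled reads
#'
#' Computes the percent of reads per source genome from the simulator's
#' truth labels (the stand-in for taxonomic read classification of real
#' data, which is out of scope here).
#'
#' @param reads a \code{seq_records} data.frame; every read must carry an
#'   \code{origin_label}.
#' @param sample_name label attached to the profile.
#' @return A named numeric vector of class \code{abundance_profile}
#'   summing to 100, with attribute \code{sample_name}.
#' @export
abundance_from_labels <- function(reads, sample_name = "sample") {
  lab <- reads$origin_label
  if (!length(lab)) stop("no reads supplied")
  if (anyNA(lab)) {
    bad <- which(is.na(lab))[1]
    stop("read '", reads$id[bad], "' (row ", bad,
         ") carries no origin label")
  }
  tab <- table(lab)
  out <- 100 * as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  structure(out, sample_name = sample_name, class = "abundance_profile")
}

#' Per-genome bias records: abundance fold change between two samples
#'
#' For each genome in the union of the two profiles (a genome absent from
#' a profile has abundance 0), computes the fold change
#' CL abundance / CE abundance and its log10.  Genomes with zero
#' abundance in a sample get a sentinel instead of a fold change:
#' \code{CE_0} (zero in the crude extract; takes precedence when both are
#' zero) or \code{CL_0} (zero in the cosmid library).
#'
#' @param profile_CE abundance profile of the crude-extract sample
#'   (named numeric, percent).
#' @param profile_CL abundance profile of the cosmid-library sample.
#' @return A data.frame of class \code{bias_records} with columns
#'   \code{genome_id}, \code{abundance_CE}, \code{abundance_CL},
#'   \code{fold_change}, \code{log10_fold_change}, \code{sentinel}
#'   (\code{"none"}, \code{"CE_0"} or \code{"CL_0"}).
#' @examples
#' compute_bias(c(rbromii = 7, rest = 93), c(rbromii = 0.01, rest = 99.99))
#' @export
compute_bias <- function(profile_CE, profile_CL) {
  genomes <- union(names(profile_CE), names(profile_CL))
  if (is.null(genomes)) stop("profiles must be named by genome")
  ce <- unname(unclass(profile_CE)[genomes])
  cl <- unname(unclass(profile_CL)[genomes])
  ce[is.na(ce)] <- 0
  cl[is.na(cl)] <- 0
  sentinel <- ifelse(ce == 0, "CE_0", ifelse(cl == 0, "CL_0", "none"))
  fc <- ifelse(sentinel == "none", cl / ce, NA_real_)
  out <- data.frame(genome_id = genomes, abundance_CE = ce,
                    abundance_CL = cl, fold_change = fc,
                    log10_fold_change = log10(fc), sentinel = sentinel,
                    stringsAsFactors = FALSE)
  class(out) <- c("bias_records", "data.frame")
  out
}

#' GC and rpoD-consensus profile of genomes
#'
#' For each genome, computes the percent GC and the number of rpoD
#' consensus sites (both strands), both raw and normalized to genome size
#' (sites per Mb, the primary density statistic).
#'
#' @param genomes a \code{seq_records} data.frame, a named character
#'   vector of genome sequences, a \code{community_genome}, or a
#'   \code{community}.
#' @return A data.frame of class \code{genome_profiles} with columns
#'   \code{genome_id}, \code{genome_length}, \code{gc},
#'   \code{rpoD_count}, \code{rpoD_per_mb}.
#' @export
genome_profile <- function(genomes) {
  if (inherits(genomes, "community_genome"))
    genomes <- structure(list(genomes), names = genomes$genome_id)
  if (inherits(genomes, "community") ||
      (is.list(genomes) && !is.data.frame(genomes) &&
       all(vapply(genomes, inherits, TRUE, "community_genome")))) {
    ids <- vapply(genomes, `[[`, character(1), "genome_id")
    seqs <- vapply(genomes, `[[`, character(1), "sequence")
  } else if (is.data.frame(genomes)) {
    ids <- genomes$id
    seqs <- genomes$sequence
  } else {
    seqs <- normalize_dna(genomes)
    ids <- names(genomes)
    if (is.null(ids)) ids <- paste0("g", seq_along(seqs))
  }
  if (!length(seqs)) stop("no genomes supplied")
  if (any(!nzchar(seqs))) stop("empty genome sequence")
  rpoD <- builtin_motifs()$rpoD
  len <- nchar(seqs)
  counts <- as.integer(scan_count(seqs, rpoD, strands = "both"))
  out <- data.frame(genome_id = ids, genome_length = len,
                    gc = vapply(seqs, gc_percent, numeric(1),
                                USE.NAMES = FALSE),
                    rpoD_count = counts,
                    rpoD_per_mb = counts / (len / 1e6),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("genome_profiles", "data.frame")
  out
}

#' Correlate library bias with genome GC and rpoD consensus density
#'
#' Merges bias records with genome profiles and computes Pearson and
#' Spearman correlations of log10 fold change against (a) percent GC and
#' (b) rpoD sites per Mb, over sentinel-free records only.  Sentinel
#' records (zero abundance in one sample) are excluded because a fold
#' change is undefined for them; their counts are always reported.
#'
#' @param bias_records a [compute_bias()] result.
#' @param genome_profiles a [genome_profile()] result.
#' @return A list of class \code{bias_correlation}: \code{n_used},
#'   \code{n_excluded} (named count per sentinel class),
#'   \code{estimates} (data.frame predictor x method with correlation
#'   \code{r}), \code{data} (the merged sentinel-free table).
#' @export
correlate_bias <- function(bias_records, genome_profiles) {
  merged <- merge(bias_records, genome_profiles, by = "genome_id")
  usable <- merged[merged$sentinel == "none", , drop = FALSE]
  excl <- table(factor(merged$sentinel, c("CE_0", "CL_0")))
  if (nrow(usable) < 3L)
    stop("need at least 3 sentinel-free genomes for correlation, got ",
         nrow(usable))
  est <- expand.grid(predictor = c("gc", "rpoD_per_mb"),
                     method = c("pearson", "spearman"),
                     stringsAsFactors = FALSE)
  est$r <- mapply(function(pred, meth)
    stats::cor(usable$log10_fold_change, usable[[pred]], method = meth),
    est$predictor, est$method)
  structure(list(n_used = nrow(usable),
                 n_excluded = c(CE_0 = unname(excl["CE_0"]),
                                CL_0 = unname(excl["CL_0"])),
                 estimates = est, data = usable),
            class = "bias_correlation")
}

#' @export
print.bias_correlation <- function(x, ...) {
  cat("<bias_correlation>  log10 fold change (CL/CE) vs genome features\n")
  cat(sprintf("  genomes used: %d (excluded: CE_0 = %d, CL_0 = %d)\n",
              x$n_used, x$n_excluded[["CE_0"]], x$n_excluded[["CL_0"]]))
  for (i in seq_len(nrow(x$estimates)))
    cat(sprintf("  %-12s %-9s r = %+.3f\n", x$estimates$predictor[i],
                x$estimates$method[i], x$estimates$r[i]))
  invisible(x)
}

#' Number of cloned fragments needed to represent a genome
#'
#' Genome length divided by the mean cloned-insert length, rounded to the
#' nearest integer — e.g. a 2.25 Mb genome at a ~28 kb mean insert is
#' covered by ~80 fragments.
#'
#' @param genome_length genome size in bases.
#' @param mean_insert_length mean cloned-insert length in bases.
#' @return Integer count (vectorized).
#' @examples
#' fragments_per_genome(2250000, 28000)  # 80
#' @export
fragments_per_genome <- function(genome_length, mean_insert_length) {
  if (any(genome_length <= 0) || any(mean_insert_length <= 0))
    stop("genome_length and mean_insert_length must be positive")
  as.integer(round(genome_length / mean_insert_length))
}
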