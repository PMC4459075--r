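# Generative simulator of the cosmid library-construction workflow:
# community genomes -> crude extract (fragmentation with a sheared-debris
# component) -> size selection -> cloning with promoter-dependent clone
# loss -> paired-end reads with truth labels.
#
# Clone loss model: a fragment carrying k rpoD consensus sites (both
# strands; insert orientation in the vector is random) survives cloning
# with probability exp(-lambda * k), i.e. an independent per-promoter
# hazard.  The simplest monotone form, and it makes lambda recoverable
# from the truth tables.

#' Specify a synthetic community
#'
#' One row per genome: identifier, genome length, target GC fraction,
#' number of rpoD consensus sites to plant, and the genome's share of
#' community DNA.  Shares are normalized to sum to 1.
#'
#' @param genome_id character vector of genome names.
#' @param length integer vector of genome lengths (bases).
#' @param gc numeric vector of target GC fractions in (0, 1).
#' @param planted_rpoD integer vector: rpoD consensus sites to plant.
#' @param relative_abundance numeric vector of DNA shares (normalized).
#' @return A data.frame of class \code{community_spec}.
#' @export
community_spec <- function(genome_id, length, gc, planted_rpoD = 0L,
                           relative_abundance = 1) {
  n <- base::length(genome_id)
  out <- data.frame(genome_id = as.character(genome_id),
                    length = as.integer(length),
                    gc = as.numeric(gc),
                    planted_rpoD = rep_len(as.integer(planted_rpoD), n),
                    relative_abundance =
                      rep_len(as.numeric(relative_abundance), n),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$genome_id)) stop("genome_id values must be unique")
  if (any(out$length < 1000L)) stop("genome lengths must be >= 1000")
  if (any(out$gc <= 0 | out$gc >= 1))
    stop("gc must be a fraction strictly between 0 and 1")
  if (any(out$planted_rpoD < 0L)) stop("planted_rpoD must be >= 0")
  if (any(out$relative_abundance < 0) || sum(out$relative_abundance) <= 0)
    stop("relative abundances must be non-negative and not all zero")
  out$relative_abundance <- out$relative_abundance /
    sum(out$relative_abundance)
  class(out) <- c("community_spec", "data.frame")
  out
}

#' Simulation parameters for the library-construction workflow
#'
#' Collects every generative knob with the workflow's defaults: size
#' selection retains fragments between 40 and 70 kb, reads are 90-base
#' paired-end, and the clone-loss rate \code{retention_rate} (lambda)
#' defaults to 1 per rpoD site.  The crude extract mixes high-molecular-
#' weight fragments with a sheared-debris component of short fragments.
#'
#' @param community a [community_spec()].
#' @param n_fragments number of fragments drawn for the crude extract.
#' @param debris_fraction probability a crude fragment is sheared debris.
#' @param debris_length_range,hmw_length_range fragment length ranges
#'   (bases) for the debris and high-molecular-weight components.
#' @param size_select_range closed retention window of size selection.
#' @param retention_rate lambda, the per-rpoD-site clone-loss rate
#'   (fragment survives cloning with probability exp(-lambda * k)).
#' @param reads_per_sample read pairs sequenced per stage.
#' @param read_length read length in bases.
#' @param insert_size sequencing insert (outer distance between mates).
#' @param error_rate per-base substitution rate (0 = error-free reads).
#' @param seed integer seed controlling the whole experiment.
#' @return A list of class \code{simulation_params}.
#' @export
simulation_params <- function(community,
                              n_fragments = 2000L,
                              debris_fraction = 0.25,
                              debris_length_range = c(500L, 5000L),
                              hmw_length_range = c(30000L, 90000L),
                              size_select_range = c(40000L, 70000L),
                              retention_rate = 1,
                              reads_per_sample = 5000L,
                              read_length = 90L,
                              insert_size = 350L,
                              error_rate = 0,
                              seed = 1L) {
  stopifnot(inherits(community, "community_spec"))
  chk_range <- function(r, nm) {
    if (length(r) != 2L || any(r < 1) || r[2] < r[1])
      stop(nm, " must be c(min, max) with 1 <= min <= max")
    as.integer(r)
  }
  if (debris_fraction < 0 || debris_fraction > 1)
    stop("debris_fraction must be in [0, 1]")
  if (retention_rate < 0) stop("retention_rate (lambda) must be >= 0")
  if (error_rate < 0 || error_rate > 1)
    stop("error_rate must be in [0, 1]")
  if (insert_size < read_length)
    stop("insert_size must be at least read_length")
  structure(list(
    community = community,
    n_fragments = as.integer(n_fragments),
    debris_fraction = debris_fraction,
    debris_length_range = chk_range(debris_length_range,
                                    "debris_length_range"),
    hmw_length_range = chk_range(hmw_length_range, "hmw_length_range"),
    size_select_range = chk_range(size_select_range, "size_select_range"),
    retention_rate = retention_rate,
    reads_per_sample = as.integer(reads_per_sample),
    read_length = as.integer(read_length),
    insert_size = as.integer(insert_size),
    error_rate = error_rate,
    seed = as.integer(seed)), class = "simulation_params")
}

#' Generate one community genome with planted rpoD consensus sites
#'
#' Bases are i.i.d. with P(G) = P(C) = gc_target / 2.  Each planted site
#' is TTGACA + a random-base spacer of length uniform in 15..19 + TATAAT,
#' overwritten at a uniformly chosen non-overlapping position on a random
#' strand (minus-strand plants overwrite the reverse complement of the
#' site).  The returned genome records its measured (scanned,
#' both-strand) rpoD count, which can exceed the planted count through
#' chance background hits.
#'
#' @param length genome length in bases (>= 1000).
#' @param gc_target GC fraction in (0, 1).
#' @param planted_rpoD number of rpoD sites to plant.
#' @param genome_id identifier for the genome.
#' @param seed optional integer seed.
#' @return A list of class \code{community_genome}: \code{genome_id},
#'   \code{length}, \code{gc_target}, \code{planted_rpoD},
#'   \code{sequence}, \code{plant_starts} (0-based),
#'   \code{rpoD_measured}.
#' @export
generate_genome <- function(length, gc_target, planted_rpoD = 0L,
                            genome_id = "g1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  if (length < 1000L) stop("genome length must be >= 1000")
  if (gc_target <= 0 || gc_target >= 1)
    stop("gc_target must be strictly between 0 and 1")
  planted_rpoD <- as.integer(planted_rpoD)
  p <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
         (1 - gc_target) / 2)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p)

  plant_starts <- integer(0)
  if (planted_rpoD > 0L) {
    spans <- integer(0)
    occupied <- matrix(numeric(0), ncol = 2)  # [start, end) 0-based
    attempts <- 0L
    while (base::length(plant_starts) < planted_rpoD) {
      attempts <- attempts + 1L
      if (attempts > 1000L * planted_rpoD)
        stop("could not place ", planted_rpoD,
             " non-overlapping rpoD sites in ", length, " bases")
      spacer <- sample(15:19, 1L)
      span <- 12L + spacer
      if (span > length) stop("genome too short for a planted site")
      start <- sample.int(length - span + 1L, 1L) - 1L  # 0-based
      if (base::length(plant_starts) &&
          any(start < plant_starts + spans & start + span > plant_starts))
        next
      site <- paste0("TTGACA",
                     paste(sample(c("A", "C", "G", "T"), spacer,
                                  replace = TRUE), collapse = ""),
                     "TATAAT")
      if (sample(c(TRUE, FALSE), 1L)) site <- reverse_complement(site)
      bases[(start + 1L):(start + span)] <- strsplit(site, "")[[1]]
      plant_starts <- c(plant_starts, start)
      spans <- c(spans, span)
    }
    ord <- order(plant_starts)
    plant_starts <- plant_starts[ord]
  }
  sequence <- paste(bases, collapse = "")
  structure(list(genome_id = genome_id, length = length,
                 gc_target = gc_target, planted_rpoD = planted_rpoD,
                 sequence = sequence, plant_starts = plant_starts,
                 rpoD_measured = sum(scan_count(sequence,
                                                builtin_motifs()$rpoD))),
            class = "community_genome")
}

#' @export
print.community_genome <- function(x, ...) {
  cat("<community_genome>", x$genome_id, "\n")
  cat(sprintf("  length %d bp, target GC %.2f, realized GC %.1f%%\n",
              x$length, x$gc_target, gc_percent(x$sequence)))
  cat(sprintf("  rpoD sites: %d planted, %d measured (both strands)\n",
              x$planted_rpoD, x$rpoD_measured))
  invisible(x)
}

#' Generate all genomes of a community
#'
#' @param spec a [community_spec()].
#' @param seed optional integer seed.
#' @return A list of class \code{community}: one [generate_genome()]
#'   result per row of \code{spec}, with the spec attached as attribute
#'   \code{"spec"}.
#' @export
generate_community <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  if (!is.null(seed)) set.seed(seed)
  genomes <- lapply(seq_len(nrow(spec)), function(i)
    generate_genome(spec$length[i], spec$gc[i], spec$planted_rpoD[i],
                    genome_id = spec$genome_id[i]))
  names(genomes) <- spec$genome_id
  structure(genomes, spec = spec, class = "community")
}

# Empty fragment-pool skeleton.
empty_fragments <- function() {
  out <- data.frame(fragment_id = character(), genome_id = character(),
                    start = integer(), end = integer(), length = integer(),
                    sequence = character(), k = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("fragment_pool", "data.frame")
  out
}

#' Fragment the community into a crude DNA extract
#'
#' Draws \code{n_fragments} fragments.  The source genome of each
#' fragment is sampled proportionally to its share of community DNA
#' (\code{relative_abundance}).  With probability \code{debris_fraction}
#' the fragment length is drawn uniformly from the sheared-debris range,
#' otherwise from the high-molecular-weight range; the start is uniform
#' on the genome and fragments are truncated at the genome end.  Each
#' fragment's both-strand rpoD consensus count k is computed and cached,
#' since it drives the downstream clone-retention model.
#'
#' @param community a [generate_community()] result.
#' @param params a [simulation_params()].
#' @return A data.frame of class \code{fragment_pool} with columns
#'   \code{fragment_id}, \code{genome_id}, \code{start}, \code{end}
#'   (0-based, half-open), \code{length}, \code{sequence}, \code{k}.
#' @export
extract_crude <- function(community, params) {
  stopifnot(inherits(community, "community"),
            inherits(params, "simulation_params"))
  spec <- attr(community, "spec")
  n <- params$n_fragments
  if (n < 1L) return(empty_fragments())
  gidx <- sample.int(nrow(spec), n, replace = TRUE,
                     prob = spec$relative_abundance)
  debris <- stats::runif(n) < params$debris_fraction
  rlen <- function(range, m)
    if (m == 0L) integer(0) else
      sample.int(range[2] - range[1] + 1L, m, replace = TRUE) + range[1] - 1L
  flen <- integer(n)
  flen[debris] <- rlen(params$debris_length_range, sum(debris))
  flen[!debris] <- rlen(params$hmw_length_range, sum(!debris))
  glen <- spec$length[gidx]
  start <- vapply(glen, function(L) sample.int(L, 1L) - 1L, 1L)  # 0-based
  end <- pmin(start + flen, glen)
  seqs <- substring(vapply(community[gidx], `[[`, character(1), "sequence"),
                    start + 1L, end)
  out <- data.frame(fragment_id = sprintf("frag%06d", seq_len(n)),
                    genome_id = spec$genome_id[gidx],
                    start = start, end = end, length = end - start,
                    sequence = seqs,
                    k = as.integer(scan_count(seqs, builtin_motifs()$rpoD)),
                    stringsAsFactors = FALSE)
  class(out) <- c("fragment_pool", "data.frame")
  out
}

#' Size-select fragments into a length window
#'
#' Keeps exactly the fragments whose length lies inside the closed
#' retention window (default 40--70 kb), preserving order.
#'
#' @param fragments a \code{fragment_pool}.
#' @param size_select_range closed \code{c(min, max)} window in bases.
#' @return The retained \code{fragment_pool} (possibly empty).
#' @export
size_select <- function(fragments, size_select_range = c(40000L, 70000L)) {
  keep <- fragments$length >= size_select_range[1] &
          fragments$length <= size_select_range[2]
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_pool", "data.frame")
  out
}

#' Clone fragments with promoter-dependent loss
#'
#' Each fragment survives cloning independently with probability
#' exp(-lambda * k), where k is its cached both-strand rpoD consensus
#' count.  With lambda = 0 every fragment is retained; fragments with
#' k = 0 are always retained.
#'
#' @param fragments a \code{fragment_pool} (normally size-selected).
#' @param lambda per-site clone-loss rate (>= 0).
#' @param seed optional integer seed.
#' @return A list with \code{retained} (the surviving
#'   \code{fragment_pool}) and \code{outcomes} (the input fragment table,
#'   sequence column dropped, plus logical column \code{survived}).
#' @export
clone_library <- function(fragments, lambda = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (lambda < 0) stop("lambda must be >= 0")
  p <- exp(-lambda * fragments$k)
  survived <- stats::runif(nrow(fragments)) < p
  outcomes <- fragments[, setdiff(names(fragments), "sequence"),
                        drop = FALSE]
  outcomes$survived <- survived
  class(outcomes) <- "data.frame"
  retained <- fragments[survived, , drop = FALSE]
  rownames(retained) <- NULL
  class(retained) <- c("fragment_pool", "data.frame")
  list(retained = retained, outcomes = outcomes)
}

#' Sample paired-end reads from a fragment pool
#'
#' Fragments are sampled proportionally to their length; each pair is an
#' error-free (by default) forward read and the reverse complement of
#' the window \code{insert_size} bases downstream, mimicking short-insert
#' paired-end sequencing of the pool.  Every read carries its fragment's
#' source genome as \code{origin_label} (the simulator's truth label).
#' Fragments shorter than \code{insert_size} cannot yield a pair and are
#' skipped with a warning.
#'
#' @param fragments a \code{fragment_pool}.
#' @param n_pairs number of read pairs to sample.
#' @param read_length read length in bases.
#' @param insert_size outer distance between mate starts' window.
#' @param error_rate per-base substitution probability (0 = error-free).
#' @param seed optional integer seed.
#' @param id_prefix prefix for read identifiers.
#' @return A \code{seq_records} data.frame with \code{2 * n_pairs} rows
#'   (mates interleaved, ids suffixed \code{/1} and \code{/2}).
#' @export
simulate_reads <- function(fragments, n_pairs, read_length = 90L,
                           insert_size = 350L, error_rate = 0,
                           seed = NULL, id_prefix = "read") {
  if (!is.null(seed)) set.seed(seed)
  read_length <- as.integer(read_length)
  insert_size <- as.integer(insert_size)
  usable <- fragments$length >= insert_size
  if (!all(usable)) {
    warning(sum(!usable), " fragment(s) shorter than the insert size ",
            "were skipped for read sampling")
    fragments <- fragments[usable, , drop = FALSE]
  }
  if (!nrow(fragments)) stop("no fragments long enough to sequence")
  n_pairs <- as.integer(n_pairs)
  fidx <- sample.int(nrow(fragments), n_pairs, replace = TRUE,
                     prob = fragments$length)
  maxs <- fragments$length[fidx] - insert_size + 1L
  s <- vapply(maxs, function(m) sample.int(m, 1L), 1L)  # 1-based
  fseq <- fragments$sequence[fidx]
  fwd <- substring(fseq, s, s + read_length - 1L)
  rev <- reverse_complement(
    substring(fseq, s + insert_size - read_length, s + insert_size - 1L))
  if (error_rate > 0) {
    fwd <- mutate_bases(fwd, error_rate)
    rev <- mutate_bases(rev, error_rate)
  }
  ids <- sprintf("%s%06d", id_prefix, seq_len(n_pairs))
  origin <- fragments$genome_id[fidx]
  out <- seq_records(
    id = as.vector(rbind(paste0(ids, "/1"), paste0(ids, "/2"))),
    sequence = as.vector(rbind(fwd, rev)),
    qualities = strrep("I", read_length),
    origin_label = rep(origin, each = 2L))
  out
}

# Uniform substitution noise; each substituted base becomes one of the
# three other bases.
mutate_bases <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit)) {
      alt <- c("A", "C", "G", "T")
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(alt, b), 1L), character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Run the full library-construction experiment
#'
#' Executes the whole generative workflow under one seed: generate the
#' community, fragment it into a crude extract, size-select, clone with
#' promoter-dependent loss, and sequence all three stages (crude extract,
#' size-selected, cosmid library) as labeled paired-end reads.  Truth
#' tables record per-genome abundance at each stage and the per-fragment
#' rpoD count and cloning outcome.
#'
#' @param params a [simulation_params()].
#' @param out_dir optional directory: when given, FASTQ files, truth
#'   tables and a seed log are written there (see [run_simulate()]).
#' @return A list of class \code{library_experiment}: \code{community},
#'   \code{crude}, \code{selected}, \code{clone} (retained + outcomes),
#'   \code{reads} (list \code{crude_extract}, \code{size_selected},
#'   \code{cosmid_library}), \code{truth} (list \code{genome_table},
#'   \code{fragment_table}), \code{params}.
#' @export
run_experiment <- function(params, out_dir = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  community <- generate_community(params$community)
  crude <- extract_crude(community, params)
  selected <- size_select(crude, params$size_select_range)
  if (!nrow(selected))
    stop("size selection retained no fragments; widen hmw_length_range ",
         "or increase n_fragments")
  clone <- clone_library(selected, params$retention_rate)
  if (!nrow(clone$retained))
    stop("no fragments survived cloning; lower retention_rate or plant ",
         "fewer rpoD sites")
  reads <- list(
    crude_extract = simulate_reads(crude, params$reads_per_sample,
                                   params$read_length, params$insert_size,
                                   params$error_rate, id_prefix = "ce"),
    size_selected = simulate_reads(selected, params$reads_per_sample,
                                   params$read_length, params$insert_size,
                                   params$error_rate, id_prefix = "ss"),
    cosmid_library = simulate_reads(clone$retained, params$reads_per_sample,
                                    params$read_length, params$insert_size,
                                    params$error_rate, id_prefix = "cl"))

  spec <- attr(community, "spec")
  base_share <- function(frags) {
    b <- tapply(frags$length, factor(frags$genome_id, spec$genome_id),
                sum, default = 0)
    100 * b / sum(b)
  }
  genome_table <- data.frame(
    genome_id = spec$genome_id,
    genome_length = spec$length,
    gc_target = spec$gc,
    planted_rpoD = spec$planted_rpoD,
    rpoD_measured = vapply(community, `[[`, 1L, "rpoD_measured"),
    relative_abundance = spec$relative_abundance,
    pct_crude = as.numeric(base_share(crude)),
    pct_selected = as.numeric(base_share(selected)),
    pct_library = as.numeric(base_share(clone$retained)),
    stringsAsFactors = FALSE, row.names = NULL)

  out <- structure(list(community = community, crude = crude,
                        selected = selected, clone = clone, reads = reads,
                        truth = list(genome_table = genome_table,
                                     fragment_table = clone$outcomes),
                        params = params),
                   class = "library_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.library_experiment <- function(x, ...) {
  cat("<library_experiment>\n")
  cat(sprintf("  community: %d genomes, %.1f Mb\n",
              length(x$community),
              sum(attr(x$community, "spec")$length) / 1e6))
  cat(sprintf("  crude fragments: %d; size-selected: %d; cloned: %d\n",
              nrow(x$crude), nrow(x$selected), nrow(x$clone$retained)))
  cat(sprintf("  reads per stage: %d pairs, %d bp, lambda = %g, seed = %d\n",
              x$params$reads_per_sample, x$params$read_length,
              x$params$retention_rate, x$params$seed))
  invisible(x)
}

#' Estimate the clone-loss rate lambda from a simulation truth table
#'
#' Under the retention model P(survive | k) = exp(-lambda * k), the
#' negative log of the empirical retention frequency among fragments with
#' k rpoD sites is lambda * k.  The estimator regresses
#' -log(retention frequency) on k through the origin, weighting each k
#' group by its fragment count; groups with no survivors carry no finite
#' log and are dropped.
#'
#' @param outcomes a fragment outcome table with columns \code{k} and
#'   \code{survived} (as in \code{run_experiment()$truth$fragment_table}).
#' @return An object of class \code{retention_fit} with components
#'   \code{lambda}, \code{groups} (per-k summary), \code{n_fragments}.
#' @export
fit_retention <- function(outcomes) {
  stopifnot(all(c("k", "survived") %in% names(outcomes)))
  agg <- stats::aggregate(survived ~ k, data = outcomes,
                          FUN = function(x) c(n = length(x), p = mean(x)))
  groups <- data.frame(k = agg$k, n = agg$survived[, "n"],
                       retention = agg$survived[, "p"])
  use <- groups$k > 0 & groups$retention > 0
  if (!any(use))
    stop("cannot estimate lambda: no k > 0 group with survivors")
  y <- -log(groups$retention[use])
  kk <- groups$k[use]
  w <- groups$n[use]
  lambda <- sum(w * kk * y) / sum(w * kk^2)
  structure(list(lambda = lambda, groups = groups,
                 n_fragments = nrow(outcomes)),
            class = "retention_fit")
}

#' @export
print.retention_fit <- function(x, ...) {
  cat("<retention_fit>  per-site clone-loss rate\n")
  cat(sprintf("  lambda = %.4f  (n = %d fragments, k groups: %s)\n",
              x$lambda, x$n_fragments,
              paste(x$groups$k, collapse = ",")))
  invisible(x)
}

#' @export
coef.retention_fit <- function(object, ...) c(lambda = object$lambda)

#' @export
summary.retention_fit <- function(object, ...) {
  cat("Retention model: P(survive | k) = exp(-lambda k)\n")
  cat(sprintf("lambda = %.4f over %d fragments\n", object$lambda,
              object$n_fragments))
  print(object$groups)
  invisible(object)
}
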