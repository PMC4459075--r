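# Motif scanning over reads and genomes.
#
# Match semantics (documented prominently because overlapping counting
# would give systematically higher counts): scanning is left to right;
# at each position the spacer is extended greedily, i.e. the longest
# admissible spacer that still completes the match is reported (earlier
# spacers take precedence in multi-spacer motifs); after a hit, scanning
# resumes immediately after the hit's end, so hits never overlap; a
# conserved position matches only if the sequence base is in its
# admissible set (N never matches a conserved position; N inside a spacer
# is allowed).  These are exactly the semantics of greedy bounded
# repetition in a backtracking regular-expression engine, which is what
# executes the scan.

#' Scan one sequence for a sigma-factor consensus motif
#'
#' Finds leftmost, non-overlapping, greedy-spacer matches of \code{motif}
#' on one or both strands.  Minus-strand hits are located by scanning the
#' reverse complement and are reported with strand \code{"-"} and
#' coordinates on the forward sequence.  All coordinates are 0-based,
#' half-open.
#'
#' @param record a single-row \code{seq_records} data.frame, or a
#'   character scalar sequence.
#' @param motif a [sigma_motif()].
#' @param strands \code{"both"} (default) or \code{"forward"}.
#' @param id identifier used for \code{sequence_id} when \code{record}
#'   is a bare string.
#' @return A data.frame of hits with columns \code{sequence_id},
#'   \code{strand}, \code{start}, \code{end} (0-based, half-open, on the
#'   forward sequence), \code{spacer_lengths} (comma-joined realized
#'   spacer lengths, in motif order) and \code{matched_text} (the matched
#'   text in motif orientation).  Zero rows when there is no hit.  Hits
#'   are in ascending start order within each strand.
#' @examples
#' m <- builtin_motifs()$rpoD
#' scan_sequence(paste0("TTGACA", strrep("A", 15), "TATAAT"), m)
#' @export
scan_sequence <- function(record, motif, strands = c("both", "forward"),
                          id = "seq") {
  strands <- match.arg(strands)
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    seq <- record$sequence
    id <- record$id
  } else {
    seq <- normalize_dna(record)
  }
  rx <- motif_regex(motif)
  fwd <- scan_one_strand(seq, rx, motif)
  if (nrow(fwd)) fwd$strand <- "+"
  if (strands == "both") {
    L <- nchar(seq)
    rev <- scan_one_strand(reverse_complement(seq), rx, motif)
    if (nrow(rev)) {
      rev$strand <- "-"
      # map [s, e) on the reverse complement to forward coordinates
      newstart <- L - rev$end
      rev$end <- L - rev$start
      rev$start <- newstart
      rev <- rev[order(rev$start), , drop = FALSE]
    }
    hits <- rbind(fwd, rev)
  } else {
    hits <- fwd
  }
  if (!nrow(hits)) {
    return(data.frame(sequence_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      spacer_lengths = character(),
                      matched_text = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(sequence_id = id, strand = hits$strand, start = hits$start,
             end = hits$end, spacer_lengths = hits$spacer_lengths,
             matched_text = hits$matched_text, stringsAsFactors = FALSE,
             row.names = NULL)
}

# One-strand scan; coordinates 0-based half-open on the scanned string.
scan_one_strand <- function(seq, rx, motif) {
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(strand = character(), start = integer(),
                      end = integer(), spacer_lengths = character(),
                      matched_text = character(), stringsAsFactors = FALSE))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  cs <- attr(m, "capture.length")
  spacer <- apply(cs, 1L, paste, collapse = ",")
  data.frame(strand = NA_character_, start = starts - 1L,
             end = starts - 1L + lens, spacer_lengths = spacer,
             matched_text = substring(seq, starts, starts + lens - 1L),
             stringsAsFactors = FALSE)
}

# Vectorized hit counting (no per-hit detail); used for dataset tables and
# fragment rpoD caching.  Counts forward hits of each sequence plus, for
# strands = "both", forward hits of its reverse complement.
scan_count <- function(seqs, motif, strands = "both") {
  rx <- motif_regex(motif)
  count1 <- function(x) {
    m <- gregexpr(rx, x, perl = TRUE)
    vapply(m, function(mm) if (mm[1] == -1L) 0L else length(mm), 1L)
  }
  n <- count1(seqs)
  if (strands == "both") n <- n + count1(reverse_complement(seqs))
  n
}

# Total hit count over many (short) sequences.  Joining reads with an
# "X" separator removes the per-string regex overhead while preserving
# per-read semantics exactly: "X" can match neither a conserved position
# nor a spacer, so no match can span two reads, and the leftmost/greedy/
# non-overlap rule within each read is unchanged.
scan_count_total <- function(seqs, motif, strands = "both",
                             chunk_bases = 8e6) {
  rx <- motif_regex(motif)
  count_chunked <- function(x) {
    sizes <- nchar(x) + 1
    breaks <- c(0, which(diff(cumsum(sizes) %/% chunk_bases) > 0),
                length(x))
    breaks <- unique(breaks)
    total <- 0L
    for (i in seq_len(length(breaks) - 1L)) {
      joined <- paste(x[(breaks[i] + 1L):breaks[i + 1L]], collapse = "X")
      m <- gregexpr(rx, joined, perl = TRUE)[[1]]
      total <- total + if (m[1] == -1L) 0L else length(m)
    }
    total
  }
  n <- count_chunked(seqs)
  if (strands == "both") n <- n + count_chunked(reverse_complement(seqs))
  n
}

#' Promoter content of a read or genome dataset
#'
#' Scans every record for every motif and tabulates hit counts normalized
#' to the amount of sequence scanned (hits per Mb).  Hits are confined
#' within single records (reads are never joined), and the megabases
#' scanned count each base once regardless of the strand mode.
#'
#' @param records a \code{seq_records} data.frame.
#' @param motifs list of [sigma_motif()] objects (default all five
#'   built-ins).
#' @param strands \code{"both"} (default) or \code{"forward"}.
#' @param sample_name label stored in the table.
#' @return A data.frame of class \code{promoter_content} with columns
#'   \code{sample_name}, \code{motif}, \code{hit_count},
#'   \code{megabases_scanned}, \code{hits_per_mb}.
#' @export
scan_dataset <- function(records, motifs = builtin_motifs(),
                         strands = c("both", "forward"),
                         sample_name = "sample") {
  strands <- match.arg(strands)
  if (!is.data.frame(records)) records <- seq_records(
    paste0("s", seq_along(records)), records)
  total_bases <- sum(nchar(records$sequence))
  if (total_bases == 0)
    stop("cannot profile a dataset with zero total bases")
  mb <- total_bases / 1e6
  counts <- vapply(motifs, function(m)
    scan_count_total(records$sequence, m, strands), 1L)
  nm <- vapply(motifs, `[[`, character(1), "name")
  out <- data.frame(sample_name = sample_name, motif = nm,
                    hit_count = as.integer(counts),
                    megabases_scanned = mb,
                    hits_per_mb = counts / mb,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("promoter_content", "data.frame")
  out
}

#' Expected motif hits per Mb on an i.i.d. background
#'
#' Closed-form chance expectation under an i.i.d. base model with
#' P(A) = P(T) = (1 - gc)/2 and P(G) = P(C) = gc/2: the per-position
#' match probability is (number of admissible spacer-length combinations)
#' times the product over conserved positions of the probability that the
#' base falls in the position's admissible set; the expectation per Mb is
#' that probability times 1e6, doubled when both strands are scanned.
#' Overlap corrections are ignored (rare-motif regime).  This quantifies
#' how strongly AT-rich genomes are enriched for sigma-70 promoter-like
#' sequences purely by chance.
#'
#' @param motif a [sigma_motif()].
#' @param gc GC content as a fraction, strictly between 0 and 1.
#' @param strands \code{"both"} (default) or \code{"forward"}.
#' @return Expected hits per megabase (numeric scalar).
#' @examples
#' expected_hits_per_mb(builtin_motifs()$rpoD, 0.5)  # ~0.596
#' @export
expected_hits_per_mb <- function(motif, gc, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) ||
      gc <= 0 || gc >= 1)
    stop("gc must be a fraction strictly between 0 and 1")
  p_base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  p_match <- prod(vapply(unlist(motif$blocks), function(set)
    sum(p_base[strsplit(set, "")[[1]]]), numeric(1)))
  combos <- prod(vapply(motif$spacers, function(sp)
    sp[2] - sp[1] + 1L, 1L))
  per_mb <- combos * p_match * 1e6
  if (strands == "both") per_mb <- 2 * per_mb
  per_mb
}
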