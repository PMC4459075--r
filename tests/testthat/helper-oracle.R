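# Independent brute-force scan oracle: enumerates every (start,
# spacer-vector) candidate by direct per-position character comparison
# and applies the leftmost / greedy-spacer / non-overlap rule itself.
# Deliberately shares no code with the package's regex-based scanner.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Spacer-length vectors in match-priority order: lexicographically
# descending with the first spacer most significant (a backtracking
# engine shortens the last spacer first).
oracle_spacer_combos <- function(motif) {
  ranges <- lapply(motif$spacers, function(sp) sp[2]:sp[1])
  grid <- as.matrix(do.call(expand.grid, rev(ranges)))
  grid[, rev(seq_along(ranges)), drop = FALSE]
}

# One-strand oracle scan; 0-based half-open coordinates on the scanned
# string.  Returns a data.frame(start, end, spacer_lengths).
oracle_scan_strand <- function(seq, motif) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  blocks <- lapply(motif$blocks, strsplit, split = "")
  block_len <- vapply(motif$blocks, length, 1L)
  span_min <- sum(block_len) + sum(vapply(motif$spacers, `[`, 1L, 1L))
  empty <- data.frame(start = integer(), end = integer(),
                      spacer_lengths = character(),
                      stringsAsFactors = FALSE)
  if (L < span_min) return(empty)

  # candidate starts where block 1 matches (vectorized)
  n_cand <- L - block_len[1] + 1L
  ok <- rep(TRUE, n_cand)
  for (j in seq_len(block_len[1]))
    ok <- ok & chars[seq_len(n_cand) + j - 1L] %in% blocks[[1]][[j]]
  cand <- which(ok)

  combos <- oracle_spacer_combos(motif)
  hits <- empty
  cursor <- 1L
  for (st in cand) {
    if (st < cursor) next
    for (ci in seq_len(nrow(combos))) {
      sp <- combos[ci, ]
      pos <- st + block_len[1]
      fail <- FALSE
      for (b in seq_along(motif$spacers)) {
        pos <- pos + sp[b]
        bl <- blocks[[b + 1L]]
        if (pos + block_len[b + 1L] - 1L > L) { fail <- TRUE; break }
        for (j in seq_len(block_len[b + 1L])) {
          if (!(chars[pos + j - 1L] %in% bl[[j]])) { fail <- TRUE; break }
        }
        if (fail) break
        pos <- pos + block_len[b + 1L]
      }
      if (!fail) {
        hits <- rbind(hits, data.frame(
          start = st - 1L, end = pos - 1L,
          spacer_lengths = paste(sp, collapse = ","),
          stringsAsFactors = FALSE))
        cursor <- pos
        break
      }
    }
  }
  hits
}

# Both-strand oracle comparable with scan_sequence() output.
oracle_scan <- function(seq, motif, strands = "both") {
  fwd <- oracle_scan_strand(seq, motif)
  if (nrow(fwd)) fwd$strand <- "+"
  if (strands == "both") {
    L <- nchar(seq)
    rev <- oracle_scan_strand(cosmidbias::reverse_complement(seq), motif)
    if (nrow(rev)) {
      rev$strand <- "-"
      newstart <- L - rev$end
      rev$end <- L - rev$start
      rev$start <- newstart
    }
    out <- rbind(fwd, rev)
  } else {
    out <- fwd
  }
  if (!nrow(out))
    return(data.frame(strand = character(), start = integer(),
                      end = integer(), spacer_lengths = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$strand, out$start),
             c("strand", "start", "end", "spacer_lengths")]
  rownames(out) <- NULL
  out
}

# Reduce a scan_sequence() result to the oracle's comparable columns.
hits_for_compare <- function(hits) {
  out <- hits[order(hits$strand, hits$start),
              c("strand", "start", "end", "spacer_lengths")]
  rownames(out) <- NULL
  out
}
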