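# Host / vector read subtraction at perfect identity.
#
# A read is removed iff its full sequence occurs exactly (100 % identity
# over the whole read, either strand) in one of the reference sequences.
# This is the strictest reading of a "conservative" perfect-identity
# contamination screen: no partial-span matches, no mismatches, and reads
# containing N can never be removed (N cannot match at 100 % identity).
# References flagged circular are matched across the origin junction.

#' Build an exact-match window index over reference sequences
#'
#' Answers the question "does this fixed-length window occur anywhere in
#' any reference, on either strand" exactly.  Circular references are
#' extended by their first \code{read_length - 1} bases so that windows
#' spanning the origin junction are found.
#'
#' @param references a \code{seq_records} data.frame, named character
#'   vector, or \code{DNAStringSet} of reference sequences (e.g. the host
#'   genome and the cloning-ready vector).
#' @param read_length window length the index answers for.
#' @param circular logical, recycled over references; TRUE for circular
#'   molecules (plasmids, vectors).
#' @return An object of class \code{reference_index}.
#' @export
build_reference_index <- function(references, read_length,
                                  circular = FALSE) {
  refs <- as_reference_set(references)
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("read_length must be positive")
  if (all(Biostrings::width(refs) < read_length))
    stop("read_length (", read_length,
         ") is longer than every reference sequence")
  circular <- rep_len(as.logical(circular), length(refs))
  subjects <- extend_circular(refs, circular, read_length)
  structure(list(references = refs, subjects = subjects,
                 circular = circular, read_length = read_length),
            class = "reference_index")
}

as_reference_set <- function(references) {
  if (methods::is(references, "DNAStringSet")) return(references)
  if (is.data.frame(references)) {
    out <- Biostrings::DNAStringSet(references$sequence)
    names(out) <- references$id
    return(out)
  }
  out <- Biostrings::DNAStringSet(normalize_dna(references))
  if (is.null(names(references)))
    names(out) <- paste0("ref", seq_along(out))
  else names(out) <- names(references)
  out
}

extend_circular <- function(refs, circular, read_length) {
  seqs <- as.character(refs)
  ext <- ifelse(circular & nchar(seqs) >= read_length,
                paste0(seqs, substr(seqs, 1L, read_length - 1L)), seqs)
  out <- Biostrings::DNAStringSet(ext)
  names(out) <- names(refs)
  out
}

#' Test whether a window occurs in an indexed reference set
#'
#' @param index a [build_reference_index()] object.
#' @param window character vector of sequences of the indexed length.
#' @return Logical vector: TRUE where the window occurs in any reference,
#'   either strand.
#' @export
window_in_index <- function(index, window) {
  window <- normalize_dna(window)
  if (any(nchar(window) != index$read_length))
    stop("window length differs from indexed read_length (",
         index$read_length, ")")
  vapply(window, function(w) {
    if (grepl("N", w, fixed = TRUE)) return(FALSE)
    pats <- c(w, reverse_complement(w))
    any(vapply(pats, function(p)
      sum(Biostrings::vcountPattern(p, index$subjects, fixed = TRUE)) > 0,
      logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Remove reads matching host or vector references at 100 % identity
#'
#' A read is removed iff its entire sequence occurs exactly in one of the
#' references, on either strand; everything else is kept.  A read
#' matching several references is attributed to the first matching
#' reference in the order given and counted once (put the host genome
#' first to mirror the usual reporting order).  Mates of a pair are
#' evaluated independently; reads containing N are never removed.
#'
#' @param reads a \code{seq_records} data.frame (e.g. from
#'   [read_fastq()]); mixed read lengths are indexed per observed length.
#' @param references reference sequences, as in
#'   [build_reference_index()], in attribution order.
#' @param circular logical, recycled over references; circular references
#'   are matched across the origin junction.
#' @return A list with elements \code{kept} (the surviving
#'   \code{seq_records}) and \code{report} (a \code{subtraction_report}:
#'   \code{total_reads}, \code{removed} named per reference,
#'   \code{removed_percent}, \code{kept_reads}).
#' @export
subtract_reads <- function(reads, references, circular = FALSE) {
  refs <- as_reference_set(references)
  circular <- rep_len(as.logical(circular), length(refs))
  n <- nrow(reads)
  removed_by <- rep(0L, length(refs))
  names(removed_by) <- names(refs)
  hit_ref <- rep(NA_integer_, n)

  lens <- nchar(reads$sequence)
  eligible <- !grepl("N", reads$sequence, fixed = TRUE)
  for (len in unique(lens[eligible])) {
    idx <- which(eligible & lens == len)
    if (!length(idx)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads$sequence[idx]))
    subjects <- extend_circular(refs, circular, len)
    for (r in seq_along(subjects)) {
      if (Biostrings::width(subjects)[r] < len) next
      subj <- subjects[[r]]
      hit <- union(Biostrings::whichPDict(pd, subj),
                   Biostrings::whichPDict(
                     pd, Biostrings::reverseComplement(subj)))
      take <- idx[hit]
      hit_ref[take] <- pmin(hit_ref[take], r, na.rm = TRUE)
    }
  }
  removed_tab <- table(factor(hit_ref, levels = seq_along(refs)))
  removed_by[] <- as.integer(removed_tab)
  kept <- reads[is.na(hit_ref), , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("seq_records", "data.frame")
  report <- structure(list(
    total_reads = n,
    removed = removed_by,
    removed_percent = if (n > 0) 100 * sum(removed_by) / n else 0,
    kept_reads = n - sum(removed_by)), class = "subtraction_report")
  list(kept = kept, report = report)
}

#' @export
print.subtraction_report <- function(x, ...) {
  cat("<subtraction_report>\n")
  cat("  total reads:  ", x$total_reads, "\n")
  for (nm in names(x$removed))
    cat("  removed (", nm, "): ", x$removed[[nm]], "\n", sep = "")
  cat(sprintf("  removed %%:    %.2f\n", x$removed_percent))
  cat("  kept reads:   ", x$kept_reads, "\n")
  invisible(x)
}
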