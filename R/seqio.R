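# Sequence I/O and elementary sequence statistics.
#
# Records are kept as a plain data.frame ("seq_records") with one row per
# sequence: id, sequence, qualities (NA when absent), origin_label (NA when
# absent).  The closed alphabet is {A,C,G,T,N}; any other IUPAC ambiguity
# code is mapped to N on ingestion so that downstream motif scanning never
# has to reason about partial ambiguity.

#' Construct a set of sequence records
#'
#' Builds the record container used throughout the package: one row per
#' named nucleotide sequence (genome, fragment or read), with optional
#' per-base qualities (carried but never interpreted) and an optional
#' truth label naming the source genome (simulator provenance).
#'
#' Sequences are uppercased and any character outside \{A,C,G,T,N\} is
#' mapped to N, keeping the alphabet closed for the motif scanner.
#'
#' @param id character vector of sequence identifiers.
#' @param sequence character vector of DNA sequences.
#' @param qualities optional character vector of per-base quality strings;
#'   must match sequence lengths where not NA.
#' @param origin_label optional character vector of source-genome labels.
#' @return A data.frame of class \code{seq_records} with columns
#'   \code{id}, \code{sequence}, \code{qualities}, \code{origin_label}.
#' @examples
#' seq_records("r1", "acgtr")$sequence  # "ACGTN"
#' @export
seq_records <- function(id, sequence, qualities = NULL, origin_label = NULL) {
  id <- as.character(id)
  sequence <- normalize_dna(sequence)
  n <- length(id)
  if (length(sequence) == 1L && n > 1L) sequence <- rep(sequence, n)
  if (length(sequence) != n)
    stop("id and sequence must have the same length")
  if (!is.null(qualities) && length(qualities) == 1L && n > 1L)
    qualities <- rep(qualities, n)
  if (!is.null(origin_label) && length(origin_label) == 1L && n > 1L)
    origin_label <- rep(origin_label, n)
  if (any(!nzchar(sequence))) {
    bad <- id[!nzchar(sequence)][1]
    stop("empty sequence for record '", bad, "'")
  }
  if (is.null(qualities)) qualities <- rep(NA_character_, n)
  if (is.null(origin_label)) origin_label <- rep(NA_character_, n)
  qualities <- as.character(qualities)
  origin_label <- as.character(origin_label)
  bad <- which(!is.na(qualities) & nchar(qualities) != nchar(sequence))
  if (length(bad))
    stop("quality string length differs from sequence length for record '",
         id[bad[1]], "' (record ", bad[1], ")")
  out <- data.frame(id = id, sequence = sequence, qualities = qualities,
                    origin_label = origin_label, stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

# Uppercase and close the alphabet to {A,C,G,T,N}.
normalize_dna <- function(x) {
  x <- toupper(as.character(x))
  # IUPAC ambiguity codes, U, and gap-ish characters all collapse to N
  chartr("URYSWKMBDHV", "NNNNNNNNNNN", x)
}

#' Read a FASTA file into sequence records
#'
#' Sequences are uppercased and non-\{A,C,G,T,N\} characters mapped to N.
#' The identifier is the first whitespace-delimited token of the header;
#' a header token of the form \code{origin=<genome>} (written by the
#' simulator) is recovered into \code{origin_label}.
#'
#' @param path path to a FASTA file (gzip-transparent).
#' @return A \code{seq_records} data.frame (zero rows for an empty file).
#' @seealso [read_fastq()], [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  headers <- names(set)
  if (length(set) && (is.null(headers) || any(!nzchar(headers))))
    stop("malformed FASTA in '", path, "': record ",
         which(!nzchar(headers))[1], " has an empty header")
  seqs <- as.character(set)
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stop("empty sequence for record '", sub("\\s.*", "", headers[empty[1]]),
         "' in '", path, "'")
  if (!length(set))
    return(seq_records(character(), character()))
  seq_records(id = sub("\\s.*", "", headers), sequence = seqs,
              origin_label = header_origin(headers))
}

#' Read a 4-line FASTQ file into sequence records
#'
#' Enforces equal sequence/quality lengths and complains, with the record
#' index, about truncated records.  Header \code{origin=} tokens are
#' recovered into \code{origin_label} (see [read_fasta()]).
#'
#' @param path path to a FASTQ file (gzip-transparent).
#' @return A \code{seq_records} data.frame with qualities populated.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (!length(lines)) return(seq_records(character(), character()))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at record index ",
         length(lines) %/% 4L + 1L, " in '", path, "'")
  i <- seq(1L, length(lines), by = 4L)
  headers <- lines[i]
  plus <- lines[i + 2L]
  if (any(substr(headers, 1L, 1L) != "@") || any(substr(plus, 1L, 1L) != "+"))
    stop("malformed FASTQ in '", path, "' at record index ",
         which(substr(headers, 1L, 1L) != "@" |
               substr(plus, 1L, 1L) != "+")[1])
  seqs <- lines[i + 1L]
  quals <- lines[i + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("sequence/quality length mismatch at record index ", bad[1],
         " in '", path, "'")
  headers <- sub("^@", "", headers)
  seq_records(id = sub("\\s.*", "", headers), sequence = seqs,
              qualities = quals, origin_label = header_origin(headers))
}

header_origin <- function(headers) {
  m <- regmatches(headers, regexpr("origin=[^\\s]+", headers, perl = TRUE))
  out <- rep(NA_character_, length(headers))
  hit <- grepl("origin=", headers, fixed = TRUE)
  out[hit] <- sub("^origin=", "", m)
  out
}

#' Write sequence records to FASTA
#'
#' @param records a \code{seq_records} data.frame.
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- paste0(">", records$id[i],
                  if (!is.na(records$origin_label[i]))
                    paste0(" origin=", records$origin_label[i]) else "")
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(hdr, substring(s, starts,
                                pmin(starts + width - 1L, nchar(s)))), con)
  }
  invisible(path)
}

#' Write sequence records to 4-line FASTQ
#'
#' Records without qualities are written with a uniform placeholder
#' quality ("I").  Origin labels are written as an \code{origin=} header
#' token so that truth labels survive a round trip through FASTQ.
#'
#' @param records a \code{seq_records} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(records, path) {
  qual <- records$qualities
  miss <- is.na(qual)
  qual[miss] <- vapply(nchar(records$sequence[miss]),
                       function(n) strrep("I", n), character(1))
  hdr <- paste0("@", records$id,
                ifelse(is.na(records$origin_label), "",
                       paste0(" origin=", records$origin_label)))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(as.vector(rbind(hdr, records$sequence, "+", qual)), con)
  invisible(path)
}

#' Pooled GC content of a set of sequences, in percent
#'
#' Computes 100 * (G + C) / (A + C + G + T) pooled over all records;
#' N bases are excluded from both numerator and denominator, so sheared
#' debris or masked bases cannot distort the profile.  Summaries report
#' this to one decimal place.
#'
#' @param x a \code{seq_records} data.frame or a character vector of
#'   sequences.
#' @return GC percentage (numeric scalar).
#' @examples
#' gc_percent(c("GCAT", "ATAT"))  # 25
#' @export
gc_percent <- function(x) {
  counts <- base_counts(x)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0)
    stop("GC content undefined: no unambiguous (A/C/G/T) bases in input")
  unname(100 * sum(counts[c("G", "C")]) / denom)
}

#' AT content in percent (complement of [gc_percent()])
#' @inheritParams gc_percent
#' @return AT percentage (numeric scalar).
#' @export
at_percent <- function(x) {
  counts <- base_counts(x)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0)
    stop("AT content undefined: no unambiguous (A/C/G/T) bases in input")
  unname(100 * sum(counts[c("A", "T")]) / denom)
}

base_counts <- function(x) {
  seqs <- if (is.data.frame(x)) x$sequence else normalize_dna(x)
  if (!length(seqs)) stop("no sequences supplied")
  af <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs),
                                      baseOnly = TRUE)
  counts <- colSums(af)
  names(counts)[names(counts) == "other"] <- "N"
  counts
}

#' Reverse complement of DNA sequences
#'
#' Standard complement over \{A,C,G,T\} with N mapped to N, reversed.
#'
#' @param sequence character vector of sequences over \{A,C,G,T,N\}.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("TTGACA")  # "TGTCAA"
#' @export
reverse_complement <- function(sequence) {
  sequence <- normalize_dna(sequence)
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sequence)))
}
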