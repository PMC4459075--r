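# Sigma-factor consensus motifs: a grammar of conserved blocks interleaved
# with bounded variable-length spacers, e.g. the sigma-70 (rpoD) consensus
# TTGACA N{15-19} TATAAT (-35 hexamer, spacer, -10 Pribnow box).

#' Define a sigma-factor consensus motif
#'
#' A motif is an ordered list of conserved blocks separated by bounded
#' variable-length spacers.  Each block is a string of position patterns:
#' a plain base (\code{A}) is a fixed position and a bracketed class
#' (\code{[A/T]} or \code{[AT]}) is a set of admissible bases.  Spacer
#' positions admit any base, including N; conserved positions never
#' match N.
#'
#' @param name motif name, e.g. \code{"rpoD"}.
#' @param blocks character vector of two or more block pattern strings,
#'   e.g. \code{c("TTGACA", "TATAAT")} or
#'   \code{c("TTG[A/T][A/T][A/T]", "CCCCAT[A/T]T")}.
#' @param spacers list (or single vector) of \code{c(min, max)} spacer
#'   length ranges, one per gap between consecutive blocks.  A scalar is
#'   treated as a fixed-length spacer.
#' @return An object of class \code{sigma_motif}.
#' @examples
#' rpoD <- sigma_motif("rpoD", c("TTGACA", "TATAAT"), list(c(15, 19)))
#' @export
sigma_motif <- function(name, blocks, spacers) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(blocks) < 2L)
    stop("a motif needs at least two conserved blocks")
  parsed <- lapply(blocks, parse_block)
  if (any(vapply(parsed, length, 1L) == 0L))
    stop("every block must be non-empty")
  if (!is.list(spacers)) spacers <- list(spacers)
  if (length(spacers) != length(blocks) - 1L)
    stop("need exactly one spacer range per gap between blocks (",
         length(blocks) - 1L, "), got ", length(spacers))
  spacers <- lapply(spacers, function(sp) {
    sp <- as.integer(sp)
    if (length(sp) == 1L) sp <- c(sp, sp)
    if (length(sp) != 2L || sp[1] < 0L || sp[2] < sp[1])
      stop("spacer range must be c(min, max) with 0 <= min <= max")
    if (sp[2] - sp[1] > 32L)
      stop("spacer range wider than 32 is not supported")
    sp
  })
  structure(list(name = name, blocks = parsed, spacers = spacers),
            class = "sigma_motif")
}

# "TTG[A/T][A/T]T" -> character vector of per-position admissible-base
# strings, e.g. c("T","T","G","AT","AT","T").
parse_block <- function(block) {
  block <- toupper(block)
  toks <- regmatches(block,
                     gregexpr("\\[[ACGT/]+\\]|[ACGT]", block))[[1]]
  if (!nzchar(block) || paste(toks, collapse = "") != block)
    stop("cannot parse block pattern '", block,
         "': use bases A/C/G/T and classes like [A/T]")
  vapply(toks, function(t) {
    bases <- unique(strsplit(gsub("[][/]", "", t), "")[[1]])
    if (!length(bases)) stop("empty position class in block '", block, "'")
    paste(sort(bases), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.sigma_motif <- function(x, ...) {
  cat("<sigma_motif>", x$name, "\n  pattern:", motif_pattern(x), "\n")
  invisible(x)
}

#' Human-readable pattern string of a motif
#' @param motif a \code{sigma_motif}.
#' @return A string such as \code{"TTGACA N15-19 TATAAT"}.
#' @export
motif_pattern <- function(motif) {
  fmt_block <- function(b)
    paste(ifelse(nchar(b) == 1L, b, paste0("[", b, "]")), collapse = "")
  fmt_sp <- function(sp)
    if (sp[1] == sp[2]) paste0("N", sp[1]) else paste0("N", sp[1], "-", sp[2])
  out <- fmt_block(motif$blocks[[1]])
  for (i in seq_along(motif$spacers))
    out <- paste(out, fmt_sp(motif$spacers[[i]]),
                 fmt_block(motif$blocks[[i + 1L]]))
  out
}

# Total conserved length (all blocks, spacers excluded).
motif_block_length <- function(motif)
  sum(vapply(motif$blocks, length, 1L))

# Span range of a full match: c(min, max).
motif_span_range <- function(motif) {
  bl <- motif_block_length(motif)
  smin <- sum(vapply(motif$spacers, `[`, 1L, 1L))
  smax <- sum(vapply(motif$spacers, `[`, 1L, 2L))
  c(bl + smin, bl + smax)
}

# PCRE with one capture group per spacer; greedy bounded repetition gives
# the leftmost match with the longest admissible spacer (earlier spacers
# take precedence), exactly the documented match semantics.
motif_regex <- function(motif) {
  fmt_block <- function(b)
    paste(ifelse(nchar(b) == 1L, b, paste0("[", b, "]")), collapse = "")
  out <- fmt_block(motif$blocks[[1]])
  for (i in seq_along(motif$spacers)) {
    sp <- motif$spacers[[i]]
    rep <- if (sp[1] == sp[2]) paste0("{", sp[1], "}")
           else paste0("{", sp[1], ",", sp[2], "}")
    out <- paste0(out, "([ACGTN]", rep, ")",
                  fmt_block(motif$blocks[[i + 1L]]))
  }
  out
}

#' The five built-in sigma-factor consensus motifs
#'
#' The housekeeping sigma-70 consensus plus four controls:
#' \describe{
#'   \item{rpoD}{sigma-70, TTGACA N15-19 TATAAT}
#'   \item{rpoE}{sigma-24, GGAACTT N15-19 TCAAA}
#'   \item{rpoH}{sigma-32, TTG[A/T][A/T][A/T] N13-14 CCCCAT[A/T]T}
#'   \item{rpoN}{sigma-54, TGGCA N7 TGC (a GC-rich consensus)}
#'   \item{sigABfr}{the Bacteroides primary sigma factor,
#'     TTTG N19-21 TA N2 TTTG, whose promoters E. coli does not recognize}
#' }
#' The controls matter because only promoters recognized by the E. coli
#' cloning host are expected to drive constitutive transcription and hence
#' clone loss.
#'
#' @return Named list of five \code{sigma_motif} objects.
#' @export
builtin_motifs <- function() {
  list(
    rpoD = sigma_motif("rpoD", c("TTGACA", "TATAAT"), list(c(15L, 19L))),
    rpoE = sigma_motif("rpoE", c("GGAACTT", "TCAAA"), list(c(15L, 19L))),
    rpoH = sigma_motif("rpoH", c("TTG[A/T][A/T][A/T]", "CCCCAT[A/T]T"),
                       list(c(13L, 14L))),
    rpoN = sigma_motif("rpoN", c("TGGCA", "TGC"), list(c(7L, 7L))),
    sigABfr = sigma_motif("sigABfr", c("TTTG", "TA", "TTTG"),
                          list(c(19L, 21L), c(2L, 2L)))
  )
}

#' Read motif definitions from a TSV table
#'
#' Columns: \code{name}, \code{blocks} (block patterns joined by
#' \code{";"}), \code{spacers} (ranges \code{min-max} joined by
#' \code{";"}).  [write_motif_table()] writes the same dialect.
#'
#' @param path path to the motif TSV.
#' @return Named list of \code{sigma_motif} objects.
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("name", "blocks", "spacers")
  if (!all(need %in% names(tab)))
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    blocks <- strsplit(tab$blocks[i], ";", fixed = TRUE)[[1]]
    spacers <- lapply(strsplit(tab$spacers[i], ";", fixed = TRUE)[[1]],
                      function(s) as.integer(strsplit(s, "-")[[1]]))
    sigma_motif(tab$name[i], blocks, spacers)
  })
  names(out) <- tab$name
  out
}

#' Write motif definitions to a TSV table
#' @param motifs list of \code{sigma_motif} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_motif_table <- function(motifs, path) {
  fmt_block <- function(b)
    paste(ifelse(nchar(b) == 1L, b, paste0("[", b, "]")), collapse = "")
  rows <- vapply(motifs, function(m) {
    paste(m$name,
          paste(vapply(m$blocks, fmt_block, character(1)), collapse = ";"),
          paste(vapply(m$spacers, function(sp)
            paste0(sp[1], "-", sp[2]), character(1)), collapse = ";"),
          sep = "\t")
  }, character(1))
  writeLines(c("name\tblocks\tspacers", rows), path)
  invisible(path)
}
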