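# small shared helpers

DNA_BASES <- c("A", "C", "G", "T")

#' GC content of a sequence
#'
#' Fraction of G/C bases among the A/C/G/T bases of each input string
#' (case-insensitive; other characters such as N are ignored).
#'
#' @param x character vector of sequences.
#' @return numeric vector of GC fractions in \[0, 1\]; `NaN` for strings
#'   without any A/C/G/T base.
#' @export
#' @examples
#' gc_content("GACCACCCA") # 6/9
gc_content <- function(x) {
  stopifnot(is.character(x))
  up <- toupper(x)
  gc <- nchar(gsub("[^GC]", "", up))
  acgt <- nchar(gsub("[^ACGT]", "", up))
  gc / acgt
}

#' Reverse complement of DNA strings
#'
#' @param x character vector over the DNA alphabet (ambiguity codes allowed).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sorted by (chrom, start, end)?
is_sorted_intervals <- function(df) {
  if (nrow(df) < 2L) return(TRUE)
  o <- order(df$chrom, df$start, df$end)
  identical(o, seq_len(nrow(df)))
}

sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges0 <- function(df, strand = NULL) {
  st <- if (is.null(strand)) "*" else strand
  if (length(st) == 1L) st <- rep(st, nrow(df))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = st
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
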