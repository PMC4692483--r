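#' Genome assembly container
#'
#' A light wrapper around a named character vector of chromosome sequences.
#' Case is preserved: lowercase bases mark soft-masked (repeat) sequence
#' when `softmask_as_repeat` is set, and can be turned into repeat
#' intervals with [softmask_intervals()].
#'
#' @param seqs named character vector of sequences over A/C/G/T/N (either
#'   case).
#' @param softmask_as_repeat treat lowercase runs as repeat annotation.
#' @return object of class `genome_assembly`.
#' @export
genome_assembly <- function(seqs, softmask_as_repeat = FALSE) {
  if (!is.character(seqs) || is.null(names(seqs)))
    stop("seqs must be a named character vector")
  if (any(!nzchar(names(seqs))) || anyDuplicated(names(seqs)))
    stop("chromosome names must be unique and non-empty")
  if (any(!nzchar(seqs))) stop("chromosome sequences must be non-empty")
  structure(list(seqs = seqs, softmask_as_repeat = softmask_as_repeat),
            class = "genome_assembly")
}

#' Read genome FASTA
#'
#' Loads all records of a (plain or gzipped) FASTA file, preserving case so
#' that soft-masking survives the round trip. Record names are truncated at
#' the first whitespace.
#'
#' @param path FASTA file.
#' @param softmask_as_repeat flag carried on the returned assembly.
#' @return a `genome_assembly`.
#' @export
read_genome <- function(path, softmask_as_repeat = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  nms <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nms))
    stop("duplicate FASTA record names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  genome_assembly(stats::setNames(as.character(x), nms),
                  softmask_as_repeat = softmask_as_repeat)
}

#' Write genome FASTA
#'
#' @param genome a `genome_assembly`.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_genome <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_assembly"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(genome$seqs),
                              filepath = path, width = width)
  invisible(path)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly: ", length(x$seqs), " chromosome(s), ",
      sum(nchar(x$seqs)), " bp total\n", sep = "")
  invisible(x)
}

#' Chromosome lengths
#' @param genome a `genome_assembly`.
#' @return named integer vector.
#' @export
seq_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  vapply(genome$seqs, nchar, integer(1L))
}

#' Soft-masked (lowercase) intervals of a genome
#'
#' @param genome a `genome_assembly`.
#' @return data frame of 0-based half-open intervals (`chrom`, `start`,
#'   `end`) covering all lowercase runs.
#' @export
softmask_intervals <- function(genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  out <- lapply(names(genome$seqs), function(chrom) {
    m <- gregexpr("[acgtn]+", genome$seqs[[chrom]])[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(chrom = chrom, start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + attr(m, "match.length"))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  out
}
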