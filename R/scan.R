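#' Scan a genome for binding sites from a site vocabulary
#'
#' Slides a window of the vocabulary width across every chromosome
#' (uppercased; windows containing N never match) and reports each window
#' whose string belongs to the sense set as a `+` site and each window in
#' the antisense set as a `-` site. Antisense hits store the sense partner
#' k-mer and inherit its MSS. When a window string belongs to both
#' orientations, the two records collapse onto the single higher-MSS
#' orientation (`+` on ties) unless `merge_duplicates` is disabled.
#' Matching is performed with an Aho-Corasick dictionary
#' ([Biostrings::matchPDict()]).
#'
#' @param genome a `genome_assembly`.
#' @param vocab a `site_vocabulary`.
#' @param merge_duplicates collapse exact-interval duplicates across strands
#'   (default). Disable to count both orientations separately.
#' @return data frame of binding sites sorted by (chrom, start): columns
#'   `chrom`, `start`, `end` (0-based half-open, width = vocabulary width),
#'   `strand`, `kmer` (sense orientation), `mss`.
#' @export
scan_sites <- function(genome, vocab, merge_duplicates = TRUE) {
  stopifnot(inherits(genome, "genome_assembly"),
            inherits(vocab, "site_vocabulary"))
  if (nrow(vocab$table) == 0L) stop("empty site vocabulary")
  # the Aho-Corasick dictionary is expensive to build relative to a single
  # scan, so it is memoized on the vocabulary object
  key <- if (merge_duplicates) "merged" else "full"
  cache <- vocab$cache %||% new.env(parent = emptyenv())
  if (is.null(cache[[key]])) {
    tab <- vocab$table
    if (merge_duplicates) {
      # one pattern per literal k-mer; prefer higher MSS, then '+' strand
      o <- order(tab$kmer, -tab$mss, tab$strand != "+")
      tab <- tab[o, , drop = FALSE]
      tab <- tab[!duplicated(tab$kmer), , drop = FALSE]
    }
    cache[[key]] <- list(
      tab = tab, pd = Biostrings::PDict(Biostrings::DNAStringSet(tab$kmer)))
  }
  tab <- cache[[key]]$tab
  pd <- cache[[key]]$pd
  w <- vocab$width

  res <- vector("list", length(genome$seqs))
  for (ci in seq_along(genome$seqs)) {
    chrom <- names(genome$seqs)[ci]
    s <- toupper(genome$seqs[[ci]])
    if (nchar(s) < w) {
      warning("chromosome ", chrom, " shorter than scan width ", w,
              "; no sites")
      next
    }
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(s))
    nper <- S4Vectors::elementNROWS(m)
    if (sum(nper) == 0L) next
    starts1 <- unlist(Biostrings::startIndex(m), use.names = FALSE)
    pat <- rep.int(seq_len(nrow(tab)), nper)
    res[[ci]] <- data.frame(
      chrom = chrom,
      start = starts1 - 1L,
      end = starts1 - 1L + w,
      strand = tab$strand[pat],
      kmer = tab$sense_kmer[pat],
      mss = tab$mss[pat],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      kmer = character(0), mss = numeric(0))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write binding sites as BED6
#'
#' 0-based half-open coordinates; name = sense k-mer, score =
#' `round(1000 * MSS)`, strand as called. Unsorted input is sorted with a
#' warning.
#'
#' @param sites binding-site data frame from [scan_sites()].
#' @param path output BED file.
#' @export
write_sites_bed <- function(sites, path) {
  if (!is_sorted_intervals(sites)) {
    warning("sites not sorted by (chrom, start); sorting before write")
    sites <- sort_intervals(sites)
  }
  gr <- as_granges0(sites, strand = sites$strand)
  if (nrow(sites)) {
    S4Vectors::mcols(gr)$name <- sites$kmer
    S4Vectors::mcols(gr)$score <- as.integer(round(1000 * sites$mss))
  } else {
    S4Vectors::mcols(gr)$name <- character(0)
    S4Vectors::mcols(gr)$score <- integer(0)
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read binding sites from a BED6 file written by [write_sites_bed()]
#'
#' @param path BED file.
#' @return binding-site data frame (MSS reconstructed as score/1000).
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kmer = if (length(gr)) as.character(gr$name) else character(0),
    mss = if (length(gr)) gr$score / 1000 else numeric(0),
    stringsAsFactors = FALSE
  )
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

#' Read a BED3+ interval file
#'
#' @param path BED file.
#' @param name label attached to the interval set.
#' @return data frame `chrom`, `start`, `end` (0-based half-open), plus
#'   `name`/`score`/`strand` columns when present in the file.
#' @export
read_bed <- function(path, name = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  for (col in intersect(c("name", "score"), names(S4Vectors::mcols(gr))))
    df[[col]] <- S4Vectors::mcols(gr)[[col]]
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  attr(df, "set_name") <- name
  sort_intervals(df)
}

#' Write a BED3+ interval file
#'
#' @param df data frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optional `name`, `score`, `strand` columns.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  gr <- as_granges0(df, strand = df$strand %||% NULL)
  if ("name" %in% names(df)) S4Vectors::mcols(gr)$name <- df$name
  if ("score" %in% names(df)) S4Vectors::mcols(gr)$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
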