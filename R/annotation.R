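#' Read a refFlat gene-annotation file
#'
#' UCSC refFlat dialect: 11 tab-separated columns (geneName, name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds); exon lists are comma-separated with an optional trailing
#' comma. Coordinates are 0-based half-open. Each row is validated
#' (exonCount consistency, exons sorted/non-overlapping within the
#' transcript, cds within tx).
#'
#' @param path refFlat file.
#' @return data frame of gene models with list columns `exonStarts`,
#'   `exonEnds`.
#' @export
read_refflat <- function(path) {
  if (!file.exists(path)) stop("refFlat file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 11L)
  if (length(bad))
    stop("refFlat line ", bad[1L], " has ", lengths(fields)[bad[1L]],
         " fields; expected 11")
  f <- function(i) vapply(fields, `[[`, character(1L), i)
  parse_list <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                   function(v) as.integer(v[nzchar(v)]))
  df <- data.frame(
    geneName = f(1L), name = f(2L), chrom = f(3L), strand = f(4L),
    txStart = as.integer(f(5L)), txEnd = as.integer(f(6L)),
    cdsStart = as.integer(f(7L)), cdsEnd = as.integer(f(8L)),
    exonCount = as.integer(f(9L)), stringsAsFactors = FALSE
  )
  df$exonStarts <- parse_list(f(10L))
  df$exonEnds <- parse_list(f(11L))
  for (i in seq_len(nrow(df))) {
    es <- df$exonStarts[[i]]
    ee <- df$exonEnds[[i]]
    if (length(es) != df$exonCount[i] || length(ee) != df$exonCount[i])
      stop("refFlat line ", i, ": exonCount (", df$exonCount[i],
           ") does not match exon list lengths")
    if (any(es >= ee) || is.unsorted(es, strictly = TRUE) ||
        any(es[-1L] < ee[-length(ee)]))
      stop("refFlat line ", i, ": exons must be sorted and non-overlapping")
    if (es[1L] < df$txStart[i] || ee[length(ee)] > df$txEnd[i])
      stop("refFlat line ", i, ": exons outside the transcript bounds")
    if (df$cdsStart[i] < df$txStart[i] || df$cdsEnd[i] > df$txEnd[i])
      stop("refFlat line ", i, ": cds outside the transcript bounds")
  }
  df
}

#' Write gene models as refFlat
#'
#' @param models gene-model data frame ([read_refflat()]).
#' @param path output file.
#' @export
write_refflat <- function(models, path) {
  lst <- function(v) vapply(v, function(x) paste0(paste(x, collapse = ","),
                                                  ","), character(1L))
  lines <- paste(models$geneName, models$name, models$chrom, models$strand,
                 models$txStart, models$txEnd, models$cdsStart,
                 models$cdsEnd, models$exonCount,
                 lst(models$exonStarts), lst(models$exonEnds), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# gap in bp between [s1,e1) and [s2,e2); 0 when overlapping or abutting
interval_gap <- function(s1, e1, s2, e2) pmax(s2 - e1, s1 - e2, 0L)

#' Annotate sites with nearest transcript, feature and CTCF distance
#'
#' For each site, the nearest transcript is the one minimizing the
#' unsigned gap between the site interval and the transcript body (0 when
#' overlapping); ties are broken by transcript name order and reported.
#' The feature label is `exon` if the site overlaps any exon of that
#' transcript, `intron` if it lies within the transcript otherwise, and
#' `upstream`/`downstream` relative to the transcript strand when outside.
#' When a CTCF boundary interval set is supplied, the nearest boundary
#' distance is computed analogously.
#'
#' @param sites binding-site (or cluster) data frame with `chrom`, `start`,
#'   `end`.
#' @param models gene models from [read_refflat()].
#' @param ctcf optional CTCF boundary intervals (`chrom`, `start`, `end`).
#' @return `sites` with added columns `nearest_gene`, `nearest_transcript`,
#'   `distance`, `feature`, and `ctcf_distance` when `ctcf` is given.
#' @export
annotate_sites <- function(sites, models, ctcf = NULL) {
  n <- nrow(sites)
  gene <- tx <- feat <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  if (!nrow(models)) {
    warning("empty gene-model list; sites left unannotated")
  } else {
    had_tie <- FALSE
    for (i in seq_len(n)) {
      m <- models[models$chrom == sites$chrom[i], , drop = FALSE]
      if (!nrow(m)) next
      d <- interval_gap(sites$start[i], sites$end[i], m$txStart, m$txEnd)
      best <- which(d == min(d))
      if (length(best) > 1L) {
        had_tie <- TRUE
        best <- best[order(m$name[best])]
      }
      b <- best[1L]
      gene[i] <- m$geneName[b]
      tx[i] <- m$name[b]
      dist[i] <- d[b]
      if (d[b] == 0L && sites$start[i] < m$txEnd[b] &&
          sites$end[i] > m$txStart[b]) {
        es <- m$exonStarts[[b]]
        ee <- m$exonEnds[[b]]
        in_exon <- any(sites$start[i] < ee & sites$end[i] > es)
        feat[i] <- if (in_exon) "exon" else "intron"
      } else {
        left_of <- sites$end[i] <= m$txStart[b]
        plus <- m$strand[b] == "+"
        feat[i] <- if (left_of == plus) "upstream" else "downstream"
      }
    }
    if (had_tie)
      message("equidistant transcript tie(s) broken by transcript name order")
  }
  sites$nearest_gene <- gene
  sites$nearest_transcript <- tx
  sites$distance <- dist
  sites$feature <- feat
  if (!is.null(ctcf)) {
    cd <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      cc <- ctcf[ctcf$chrom == sites$chrom[i], , drop = FALSE]
      if (nrow(cc))
        cd[i] <- min(interval_gap(sites$start[i], sites$end[i],
                                  cc$start, cc$end))
    }
    sites$ctcf_distance <- cd
  }
  sites
}

#' Assign sites to gene loci with midpoint boundaries
#'
#' Loci are gene-level hulls (the span of all transcripts sharing a gene
#' name); the boundary between neighboring loci on a chromosome is the
#' midpoint of the intergenic gap, and a site falls in the locus whose side
#' of the boundary contains the site midpoint (a site exactly on a boundary
#' goes to the left locus). Every site on a chromosome with gene models is
#' assigned to exactly one locus.
#'
#' @param sites binding-site data frame.
#' @param models gene models from [read_refflat()].
#' @param anchor_mss threshold for the high-score site count column
#'   (default 0.81).
#' @return list with `assignments` (`sites` plus a `locus` column) and
#'   `counts` (per-locus `n_sites` and `n_anchor`, the count of sites with
#'   `MSS >= anchor_mss`).
#' @export
assign_sites_to_loci <- function(sites, models, anchor_mss = 0.81) {
  hull <- stats::aggregate(cbind(start = models$txStart, end = models$txEnd),
                           by = list(locus = models$geneName,
                                     chrom = models$chrom),
                           FUN = function(x) x[1L])
  hull$start <- vapply(seq_len(nrow(hull)), function(i)
    min(models$txStart[models$geneName == hull$locus[i] &
                         models$chrom == hull$chrom[i]]), integer(1L))
  hull$end <- vapply(seq_len(nrow(hull)), function(i)
    max(models$txEnd[models$geneName == hull$locus[i] &
                       models$chrom == hull$chrom[i]]), integer(1L))
  locus <- rep(NA_character_, nrow(sites))
  for (chrom in unique(sites$chrom)) {
    h <- hull[hull$chrom == chrom, , drop = FALSE]
    si <- which(sites$chrom == chrom)
    if (!nrow(h)) {
      warning("no gene models on ", chrom, "; sites left unassigned")
      next
    }
    h <- h[order(h$start, h$end), , drop = FALSE]
    # midpoint of each intergenic gap (0-based continuous coordinate)
    bounds <- if (nrow(h) > 1L)
      (h$end[-nrow(h)] + h$start[-1L]) / 2 else numeric(0)
    mid <- (sites$start[si] + sites$end[si]) / 2
    # site exactly on a boundary goes left: count strictly-greater bounds
    pos <- vapply(mid, function(x) sum(x > bounds), integer(1L)) + 1L
    locus[si] <- h$locus[pos]
  }
  sites$locus <- locus
  assigned <- sites[!is.na(sites$locus), , drop = FALSE]
  counts <- if (nrow(assigned)) {
    agg <- stats::aggregate(
      cbind(n_sites = rep(1L, nrow(assigned)),
            n_anchor = as.integer(assigned$mss >= anchor_mss)),
      by = list(locus = assigned$locus, chrom = assigned$chrom),
      FUN = sum)
    agg[order(agg$chrom, agg$locus), , drop = FALSE]
  } else {
    data.frame(locus = character(0), chrom = character(0),
               n_sites = integer(0), n_anchor = integer(0))
  }
  list(assignments = sites, counts = counts)
}

#' Flag sites overlapping an exclusion interval set
#'
#' @param sites binding-site data frame.
#' @param intervals interval data frame (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return logical vector: `TRUE` where a site overlaps any interval by at
#'   least 1 bp.
#' @export
exclusion_overlap <- function(sites, intervals) {
  if (!nrow(sites)) return(logical(0))
  if (is.null(intervals) || !nrow(intervals))
    return(rep(FALSE, nrow(sites)))
  hits <- suppressWarnings( # disjoint seqlevel sets are a legitimate miss
    GenomicRanges::findOverlaps(as_granges0(sites), as_granges0(intervals),
                                minoverlap = 1L))
  out <- rep(FALSE, nrow(sites))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Cross-species positional-overlap filter
#'
#' Retains each cluster that overlaps, by one or more bases, any cluster
#' interval lifted over from the other species' genome (sequence content
#' is ignored; only positional overlap matters). The lifted intervals must
#' already be mapped into this assembly's coordinates.
#'
#' @param clusters cluster data frame (`chrom`, `start`, `end`).
#' @param lifted lifted cluster intervals in the same coordinates.
#' @return `clusters` restricted to rows with orthologous support, with an
#'   `ortholog_support` column added.
#' @export
ortholog_overlap_filter <- function(clusters, lifted) {
  if (!nrow(clusters)) {
    clusters$ortholog_support <- logical(0)
    return(clusters)
  }
  unknown <- setdiff(unique(lifted$chrom), unique(clusters$chrom))
  if (length(unknown) && !length(intersect(unique(lifted$chrom),
                                           unique(clusters$chrom))))
    stop("lifted intervals share no chromosome names with the clusters; ",
         "assembly mismatch? Offending names: ",
         paste(unknown, collapse = ", "))
  keep <- exclusion_overlap(clusters, lifted)
  clusters$ortholog_support <- keep
  clusters[keep, , drop = FALSE]
}
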