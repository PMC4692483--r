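#' Toy PWM with a given consensus and sharpness
#'
#' Builds a position weight matrix whose consensus base carries frequency
#' `sharpness` at every position and the three other bases share the
#' remainder equally. At `sharpness = 1` the matrix is strict (only the
#' consensus scores 1); at `sharpness = 0.25` every row is uniform and no
#' informative core exists.
#'
#' @param consensus consensus string over A/C/G/T.
#' @param sharpness consensus-base frequency in (0, 1].
#' @param name matrix identifier.
#' @param civ_min CIV threshold for core selection (see [pwm()]).
#' @return an `ci_pwm`.
#' @export
make_toy_matrix <- function(consensus, sharpness = 0.9, name = "toy",
                            civ_min = 70) {
  stopifnot(sharpness > 0, sharpness <= 1)
  bases <- strsplit(toupper(consensus), "")[[1L]]
  idx <- match(bases, DNA_BASES)
  if (anyNA(idx)) stop("consensus must be over A/C/G/T")
  freq <- matrix((1 - sharpness) / 3, nrow = length(bases), ncol = 4L)
  freq[cbind(seq_along(idx), idx)] <- sharpness
  pwm(freq, name = name, civ_min = civ_min)
}

#' Simulate a genome with a controllable GC landscape and planted sites
#'
#' Draws background bases segment by segment at the requested GC fraction
#' (G/C and A/T chosen uniformly within each class), writes the planted
#' k-mers at their offsets (minus-strand plants store the reverse
#' complement in the genome), and optionally scrubs decoys: every window
#' that matches the vocabulary without being planted is re-randomized
#' (touching only non-planted bases) until no spurious match remains.
#'
#' @param lengths named integer vector of chromosome lengths.
#' @param gc either a single GC fraction applied everywhere, or a data
#'   frame `chrom`, `start`, `end`, `gc` of piecewise-constant segments
#'   (0-based half-open; uncovered stretches fall back to 0.5).
#' @param planted data frame of planted sites: `chrom`, `start` (0-based
#'   offset), `kmer` (sense orientation, from the vocabulary), `strand`.
#'   Intervals must not overlap.
#' @param vocab `site_vocabulary`, required for scrubbing and for the MSS
#'   in the returned truth table.
#' @param scrub re-randomize unplanted vocabulary matches (needs `vocab`).
#' @param seed optional RNG seed.
#' @param max_scrub_iter bounded retries before giving up on scrubbing.
#' @return list with `genome` (a `genome_assembly`) and `truth` (the
#'   ground-truth binding-site data frame the scanner should recover).
#' @export
simulate_genome <- function(lengths, gc = 0.5, planted = NULL, vocab = NULL,
                            scrub = FALSE, seed = NULL,
                            max_scrub_iter = 50L) {
  stopifnot(!is.null(names(lengths)), all(lengths > 0))
  if (scrub && is.null(vocab))
    stop("scrubbing requires the site vocabulary")
  if (is.null(planted))
    planted <- data.frame(chrom = character(0), start = integer(0),
                          kmer = character(0), strand = character(0))
  run <- function() sim_genome_impl(lengths, gc, planted, vocab, scrub,
                                    max_scrub_iter)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

sim_genome_impl <- function(lengths, gc, planted, vocab, scrub,
                            max_scrub_iter) {
  draw_base <- function(p_gc, n) {
    is_gc <- stats::runif(n) < p_gc
    out <- character(n)
    out[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
    out[!is_gc] <- sample(c("A", "T"), sum(!is_gc), replace = TRUE)
    out
  }
  gc_at <- function(chrom, pos) { # per-position GC fraction (0-based pos)
    if (is.data.frame(gc)) {
      seg <- gc[gc$chrom == chrom, , drop = FALSE]
      p <- rep(0.5, length(pos))
      for (i in seq_len(nrow(seg))) {
        inside <- pos >= seg$start[i] & pos < seg$end[i]
        p[inside] <- seg$gc[i]
      }
      p
    } else rep(gc, length(pos))
  }

  w <- if (!is.null(vocab)) vocab$width else NULL
  seqs <- character(0)
  truth <- list()
  for (chrom in names(lengths)) {
    n <- lengths[[chrom]]
    v <- character(n)
    p <- gc_at(chrom, 0:(n - 1L))
    v[] <- draw_base(p, n)

    pl <- planted[planted$chrom == chrom, , drop = FALSE]
    planted_mask <- rep(FALSE, n)
    if (nrow(pl)) {
      pw <- nchar(pl$kmer)
      if (any(pl$start < 0L) || any(pl$start + pw > n))
        stop("planted site out of bounds on ", chrom)
      o <- order(pl$start)
      if (any(pl$start[o][-1L] < (pl$start + pw)[o][-nrow(pl)]))
        stop("planted sites overlap on ", chrom)
      for (i in seq_len(nrow(pl))) {
        written <- if (pl$strand[i] == "-")
          reverse_complement(pl$kmer[i]) else pl$kmer[i]
        ix <- pl$start[i] + seq_len(pw[i])
        v[ix] <- strsplit(written, "")[[1L]]
        planted_mask[ix] <- TRUE
      }
      mss <- if (!is.null(vocab)) unname(vocab$sense[pl$kmer]) else NA_real_
      truth[[chrom]] <- data.frame(
        chrom = chrom, start = pl$start, end = pl$start + pw,
        strand = pl$strand, kmer = pl$kmer, mss = mss,
        stringsAsFactors = FALSE
      )
    }

    if (scrub) {
      planted_iv <- if (nrow(pl))
        cbind(pl$start, pl$start + nchar(pl$kmer)) else
        matrix(integer(0), ncol = 2L)
      for (iter in seq_len(max_scrub_iter + 1L)) {
        g1 <- genome_assembly(stats::setNames(paste(v, collapse = ""), chrom))
        hits <- scan_sites(g1, vocab)
        spurious <- hits[!(hits$start %in% planted_iv[, 1L]), , drop = FALSE]
        if (!nrow(spurious)) break
        if (iter > max_scrub_iter)
          stop("could not scrub spurious vocabulary matches on ", chrom,
               " after ", max_scrub_iter, " passes; the vocabulary is too",
               " dense for this GC landscape -- lower the GC or shrink",
               " the vocabulary")
        for (i in seq_len(nrow(spurious))) {
          ix <- (spurious$start[i] + 1L):spurious$end[i]
          redraw <- ix[!planted_mask[ix]]
          v[redraw] <- draw_base(gc_at(chrom, redraw - 1L), length(redraw))
        }
      }
    }
    seqs[chrom] <- paste(v, collapse = "")
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        kmer = character(0), mss = numeric(0))
  truth <- sort_intervals(truth)
  rownames(truth) <- NULL
  list(genome = genome_assembly(seqs), truth = truth)
}

#' Lay out the planted sites of a synthetic cluster
#'
#' Spreads `length(kmers)` sites evenly over `[start, start + span)` on one
#' chromosome: the first site begins at `start`, the last ends at
#' `start + span`, and the intermediate sites are evenly spaced
#' (non-overlapping).
#'
#' @param chrom chromosome name.
#' @param start 0-based start of the cluster window.
#' @param span end-to-end span in bp.
#' @param kmers sense k-mers to plant (one site each).
#' @param strands site strands (recycled; default all `+`).
#' @return data frame suitable for the `planted` argument of
#'   [simulate_genome()].
#' @export
plan_cluster_sites <- function(chrom, start, span, kmers, strands = "+") {
  k <- length(kmers)
  w <- nchar(kmers[1L])
  stopifnot(k >= 1L, all(nchar(kmers) == w), span >= k * w)
  offsets <- if (k == 1L) start else
    start + round(seq(0L, span - w, length.out = k))
  if (any(diff(offsets) < w))
    stop("span too small to place ", k, " non-overlapping sites")
  data.frame(chrom = chrom, start = as.integer(offsets), kmer = kmers,
             strand = rep_len(strands, k), stringsAsFactors = FALSE)
}

#' Generate toy annotation matched to a synthetic genome
#'
#' Tiles `genes_per_chrom` two-exon genes across each chromosome, then
#' positions the exclusion annotation to exercise each filter branch:
#' an exon interval is placed over the first site of each cluster listed
#' in `exon_clusters`, a repeat interval over each cluster in
#' `repeat_clusters`, and the lifted-cluster BED covers exactly the
#' clusters in `lifted_clusters` (so the orthology filter retains just
#' those). Gene exons are nudged off any planted site so unlisted clusters
#' stay clean by construction.
#'
#' @param genome a `genome_assembly`.
#' @param clusters data frame of truth cluster intervals (`chrom`, `start`,
#'   `end`), e.g. the planted cluster windows.
#' @param truth_sites planted site table (used to keep tiled exons clear).
#' @param exon_clusters,repeat_clusters,lifted_clusters integer indices
#'   into `clusters`.
#' @param genes_per_chrom tiled genes per chromosome.
#' @param ctcf_spacing spacing of CTCF boundary intervals in bp.
#' @return list of data frames: `models` (refFlat-style gene models),
#'   `exons`, `repeats`, `ctcf`, `lifted`.
#' @export
make_annotation <- function(genome, clusters, truth_sites = NULL,
                            exon_clusters = integer(0),
                            repeat_clusters = integer(0),
                            lifted_clusters = integer(0),
                            genes_per_chrom = 4L, ctcf_spacing = 25000L) {
  stopifnot(inherits(genome, "genome_assembly"))
  lens <- seq_lengths(genome)
  avoid <- if (!is.null(truth_sites) && nrow(truth_sites))
    truth_sites else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))

  models <- list()
  for (chrom in names(lens)) {
    n <- lens[[chrom]]
    gw <- n %/% (2L * genes_per_chrom) # gene width; gaps of equal width
    for (g in seq_len(genes_per_chrom)) {
      txStart <- as.integer((2L * (g - 1L)) * gw)
      txEnd <- txStart + gw
      exw <- max(50L, gw %/% 20L)
      ex1 <- c(txStart, txStart + exw)
      ex2 <- c(txEnd - exw, txEnd)
      shift_clear <- function(ivl) {
        for (try in 0:20) {
          s <- ivl[1L] + try * exw
          e <- s + exw
          if (e > txEnd) break
          ov <- avoid$chrom == chrom & avoid$start < e & avoid$end > s
          if (!any(ov)) return(c(s, e))
        }
        ivl
      }
      ex1 <- shift_clear(ex1)
      ex2 <- shift_clear(ex2)
      if (ex2[1L] <= ex1[2L]) ex2 <- c(ex1[2L] + exw, ex1[2L] + 2L * exw)
      models[[length(models) + 1L]] <- data.frame(
        geneName = sprintf("gene_%s_%d", chrom, g),
        name = sprintf("tx_%s_%d.1", chrom, g),
        chrom = chrom, strand = if (g %% 2L) "+" else "-",
        txStart = txStart, txEnd = max(txEnd, ex2[2L]),
        cdsStart = ex1[1L], cdsEnd = ex2[2L], exonCount = 2L,
        stringsAsFactors = FALSE
      )
      models[[length(models)]]$exonStarts <- list(c(ex1[1L], ex2[1L]))
      models[[length(models)]]$exonEnds <- list(c(ex1[2L], ex2[2L]))
    }
  }
  models <- do.call(rbind, models)

  exon_iv <- lapply(models$exonStarts, identity)
  exons <- data.frame(
    chrom = rep(models$chrom, each = 2L),
    start = unlist(models$exonStarts),
    end = unlist(models$exonEnds)
  )
  cluster_hit <- function(idx) {
    if (!length(idx)) return(NULL)
    cl <- clusters[idx, , drop = FALSE]
    # cover the first planted site of the cluster by 1+ bp
    data.frame(chrom = cl$chrom, start = cl$start, end = cl$start + 2L)
  }
  extra_exons <- cluster_hit(exon_clusters)
  if (!is.null(extra_exons)) exons <- rbind(exons, extra_exons)
  repeats <- cluster_hit(repeat_clusters) %||%
    data.frame(chrom = character(0), start = integer(0), end = integer(0))

  ctcf <- do.call(rbind, lapply(names(lens), function(chrom) {
    at <- seq(0L, lens[[chrom]] - 1L, by = ctcf_spacing)
    data.frame(chrom = chrom, start = at, end = at + 200L)
  }))
  lifted <- if (length(lifted_clusters))
    clusters[lifted_clusters, c("chrom", "start", "end"), drop = FALSE] else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))

  list(models = models, exons = sort_intervals(exons),
       repeats = sort_intervals(repeats), ctcf = sort_intervals(ctcf),
       lifted = sort_intervals(lifted))
}
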