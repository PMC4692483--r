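#' Background sequence randomization models
#'
#' Three randomizations of a chromosome sequence used to estimate how many
#' binding sites a genomic region would carry by chance:
#'
#' * `bg_random()` -- every non-N base is redrawn uniformly from A/C/G/T
#'   (destroys all composition structure).
#' * `bg_shuffle3mer()` -- the sequence is parsed into contiguous
#'   non-overlapping 3-mers which are then shuffled; a trailing remainder of
#'   1--2 bases stays in place (preserves 3-mer and mononucleotide
#'   composition globally, homogenizes it locally).
#' * `bg_flip_gc_at()` -- every base is independently replaced by itself or
#'   its complement with probability 1/2 (G <-> C, A <-> T), which preserves
#'   the GC/AT identity of every single position and therefore the GC
#'   content of every window exactly.
#'
#' All three return a same-length uppercase sequence (`bg_shuffle3mer`
#' preserves the input text of each block); `bg_random` and `bg_flip_gc_at`
#' keep N in place. Results are deterministic given the R RNG state; set a
#' seed (or use the `seed` arguments of the pipeline wrappers) for
#' reproducibility.
#'
#' @param seq single character string over A/C/G/T/N (either case).
#' @return randomized sequence of the same length.
#' @name background_models
NULL

FLIP_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# byte-level lookup tables (sequences are manipulated as integer byte codes
# for speed; ~100 kb chromosomes are randomized thousands of times)
.code <- function(ch) utf8ToInt(ch)
UPPER_LUT <- {
  lut <- integer(128)
  lut[seq_len(128)] <- seq_len(128) - 1L
  for (b in c("a", "c", "g", "t", "n"))
    lut[.code(b) + 1L] <- .code(toupper(b))
  lut
}
COMP_LUT <- {
  lut <- UPPER_LUT
  for (b in names(FLIP_COMPLEMENT))
    lut[.code(b) + 1L] <- .code(FLIP_COMPLEMENT[[b]])
  for (b in names(FLIP_COMPLEMENT))
    lut[.code(tolower(b)) + 1L] <- .code(FLIP_COMPLEMENT[[b]])
  lut
}

#' @rdname background_models
#' @export
bg_random <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- UPPER_LUT[utf8ToInt(seq) + 1L]
  n <- length(x)
  out <- utf8ToInt("ACGT")[sample.int(4L, n, replace = TRUE)]
  keep <- !(x %in% utf8ToInt("ACGT")) # N (and any other byte) kept in place
  out[keep] <- x[keep]
  intToUtf8(out)
}

#' @rdname background_models
#' @export
bg_shuffle3mer <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  n3 <- n %/% 3L
  if (n3 < 2L) return(seq)
  blocks <- substring(seq, seq(1L, by = 3L, length.out = n3),
                      seq(3L, by = 3L, length.out = n3))
  tail <- if (n %% 3L) substr(seq, 3L * n3 + 1L, n) else ""
  paste0(paste(sample(blocks), collapse = ""), tail)
}

#' @rdname background_models
#' @export
bg_flip_gc_at <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  raw <- utf8ToInt(seq)
  x <- UPPER_LUT[raw + 1L]
  bad <- !(x %in% utf8ToInt("ACGTN"))
  if (any(bad))
    stop("sequence contains characters outside A/C/G/T/N: ",
         paste(unique(intToUtf8(raw[bad], multiple = TRUE)), collapse = ""))
  flip <- stats::runif(length(x)) < 0.5
  x[flip] <- COMP_LUT[x[flip] + 1L]
  intToUtf8(x)
}

# apply a background model to every chromosome of an assembly
randomize_genome <- function(genome, model = c("flip_gc_at", "shuffle3mer",
                                               "random")) {
  model <- match.arg(model)
  fn <- switch(model, flip_gc_at = bg_flip_gc_at,
               shuffle3mer = bg_shuffle3mer, random = bg_random)
  genome_assembly(vapply(genome$seqs, fn, character(1L)),
                  softmask_as_repeat = FALSE)
}

#' Flank GC profile of binding sites
#'
#' GC fraction of the sequence flanking each site (`flank` bp on each side,
#' the site bases themselves excluded). Sites too close to a chromosome end
#' for a full flank are excluded and counted. Evaluating the profile of the
#' native site coordinates on a randomized genome shows whether the
#' background model preserves the GC context of the sites: the GC/AT flip
#' model reproduces it exactly, while base randomization and 3-mer
#' shuffling homogenize it.
#'
#' @param sites binding-site data frame (`chrom`, `start`, `end`).
#' @param genome a `genome_assembly` (native or randomized).
#' @param flank flank width in bp per side (default 50).
#' @return object of class `gc_profile`: list with `per_site` (data frame
#'   with a `gc` column), `mean`, `sem` (standard error of the mean across
#'   sites), `flank` and `n_excluded`.
#' @export
gc_context_profile <- function(sites, genome, flank = 50L) {
  stopifnot(inherits(genome, "genome_assembly"))
  lens <- seq_lengths(genome)
  if (nrow(sites) && !all(sites$chrom %in% names(lens)))
    stop("sites reference chromosomes absent from the genome")
  ok <- sites$start - flank >= 0L & sites$end + flank <= lens[sites$chrom]
  kept <- sites[ok, , drop = FALSE]
  gc <- numeric(nrow(kept))
  if (nrow(kept)) {
    seqs <- genome$seqs[kept$chrom]
    left <- substr(seqs, kept$start - flank + 1L, kept$start)
    right <- substr(seqs, kept$end + 1L, kept$end + flank)
    both <- toupper(paste0(left, right))
    gc <- nchar(gsub("[^GC]", "", both)) / (2L * flank)
  }
  kept$gc <- gc
  structure(
    list(per_site = kept,
         mean = if (length(gc)) mean(gc) else NA_real_,
         sem = if (length(gc) > 1L) stats::sd(gc) / sqrt(length(gc))
               else NA_real_,
         flank = flank,
         n_excluded = sum(!ok)),
    class = "gc_profile"
  )
}

#' @export
print.gc_profile <- function(x, ...) {
  cat("gc_profile: ", nrow(x$per_site), " sites (", x$n_excluded,
      " excluded), flank ", x$flank, " bp, mean GC ",
      formatC(x$mean, digits = 3, format = "f"), " +/- ",
      formatC(x$sem, digits = 4, format = "f"), " (SEM)\n", sep = "")
  invisible(x)
}

#' Pool binding-site positions from raw background genomes
#'
#' Generates `n_raw` randomized copies of the genome under the chosen
#' background model, scans each with the site vocabulary, and pools every
#' hit (coordinates, k-mer, MSS) into a master list of possible site
#' positions. Duplicate coordinates arising in different replicates are
#' retained; sampling during reconstruction is uniform over pool entries.
#' Per-replicate total site counts are recorded for comparison against the
#' native count (randomized genomes typically carry fewer sites than the
#' native sequence, which motivates the composition-correction step).
#'
#' @param genome native `genome_assembly`.
#' @param vocab a `site_vocabulary`.
#' @param model background model name.
#' @param n_raw number of raw background genomes (the full-scale analysis
#'   uses 1000; the composition correction makes downstream statistics
#'   insensitive to this count).
#' @param seed optional RNG seed for reproducibility.
#' @return object of class `site_pool`: list with `sites` (pooled hits with
#'   a `replicate` column), `replicate_counts` (per-replicate totals),
#'   `model`, `n_raw`.
#' @export
build_site_pool <- function(genome, vocab,
                            model = c("flip_gc_at", "shuffle3mer", "random"),
                            n_raw = 1000L, seed = NULL) {
  model <- match.arg(model)
  run <- function() {
    hits <- vector("list", n_raw)
    counts <- integer(n_raw)
    for (r in seq_len(n_raw)) {
      bg <- randomize_genome(genome, model)
      s <- scan_sites(bg, vocab)
      counts[r] <- nrow(s)
      if (nrow(s)) {
        s$replicate <- r
        hits[[r]] <- s
      }
    }
    list(hits = do.call(rbind, hits), counts = counts)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  sites <- res$hits
  if (is.null(sites)) {
    warning("no background sites found in any replicate; ",
            "the vocabulary cannot occur under this model/genome")
    sites <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        kmer = character(0), mss = numeric(0),
                        replicate = integer(0))
  }
  structure(
    list(sites = sites,
         replicate_counts = data.frame(replicate = seq_len(n_raw),
                                       n_sites = res$counts),
         model = model, n_raw = n_raw),
    class = "site_pool"
  )
}

#' @export
print.site_pool <- function(x, ...) {
  cat("site_pool (", x$model, "): ", nrow(x$sites), " pooled hits from ",
      x$n_raw, " raw backgrounds (median ",
      stats::median(x$replicate_counts$n_sites), " sites/replicate)\n",
      sep = "")
  invisible(x)
}

#' Reconstruct composition-corrected background site maps
#'
#' Builds `n_replicates` background site maps such that every replicate
#' contains *exactly* the native chromosome's composition of sites: for
#' each k-mer, the native count of positions is drawn from that k-mer's
#' pooled background positions, without coordinate reuse within a
#' replicate. Coordinate collisions are resolved by rejection resampling.
#' If a k-mer's native count exceeds its distinct pooled positions, the
#' missing positions are borrowed from pooled sites of the same MSS class
#' (MSS rounded to 0.01) and relabeled with the native k-mer so the
#' per-k-mer composition invariant still holds exactly (with a warning);
#' if even the MSS class cannot supply enough distinct positions the
#' function stops and advises a larger `n_raw`.
#'
#' @param pool a `site_pool`.
#' @param native_sites native binding-site data frame ([scan_sites()]).
#' @param n_replicates number of corrected background maps (default 100).
#' @param seed optional RNG seed.
#' @param max_attempts rejection-resampling cap per site.
#' @return object of class `background_ensemble`: list with `sites`
#'   (columns of `native_sites` plus `replicate`), `n_replicates`,
#'   `native_composition` (per chrom x k-mer counts), `model`, `n_raw`.
#' @export
reconstruct_backgrounds <- function(pool, native_sites, n_replicates = 100L,
                                    seed = NULL, max_attempts = 1000L) {
  stopifnot(inherits(pool, "site_pool"))
  if (!nrow(native_sites)) stop("native site set is empty")
  comp <- stats::aggregate(list(count = native_sites$start),
                           by = list(chrom = native_sites$chrom,
                                     kmer = native_sites$kmer),
                           FUN = length)
  # candidate pool entries per (chrom, k-mer), computed once
  warned <- character(0)
  cand_list <- vector("list", nrow(comp))
  for (i in seq_len(nrow(comp))) {
    chrom <- comp$chrom[i]
    kmer <- comp$kmer[i]
    need <- comp$count[i]
    cand <- pool$sites[pool$sites$chrom == chrom &
                         pool$sites$kmer == kmer, , drop = FALSE]
    if (length(unique(cand$start)) < need) {
      # fallback: same-MSS-class positions, relabeled with this k-mer
      mss_k <- native_sites$mss[match(kmer, native_sites$kmer)]
      cls <- round(pool$sites$mss, 2L) == round(mss_k, 2L)
      cand <- pool$sites[pool$sites$chrom == chrom & cls, , drop = FALSE]
      cand$kmer <- rep_len(kmer, nrow(cand))
      cand$mss <- rep_len(mss_k, nrow(cand))
      if (length(unique(cand$start)) < need)
        stop("cannot reconstruct backgrounds: k-mer ", kmer, " on ",
             chrom, " needs ", need, " distinct positions but the pool",
             " (even within its MSS class) has fewer; increase n_raw")
      warned <- union(warned, kmer)
    }
    cand_list[[i]] <- cand[, c("chrom", "start", "end", "strand",
                               "kmer", "mss"), drop = FALSE]
  }
  if (length(warned))
    warning("pool too shallow for k-mer(s) ",
            paste(warned, collapse = ", "),
            "; positions borrowed from the same MSS class")
  build <- function() {
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      rows <- vector("list", nrow(comp))
      used <- new.env(parent = emptyenv()) # chrom:start -> TRUE
      for (i in seq_len(nrow(comp))) {
        chrom <- comp$chrom[i]
        kmer <- comp$kmer[i]
        need <- comp$count[i]
        cand <- cand_list[[i]]
        sel <- integer(0)
        for (s in seq_len(need)) {
          ok <- FALSE
          for (att in seq_len(max_attempts)) {
            j <- sample.int(nrow(cand), 1L)
            key <- paste0(chrom, ":", cand$start[j])
            if (is.null(used[[key]])) {
              used[[key]] <- TRUE
              sel <- c(sel, j)
              ok <- TRUE
              break
            }
          }
          if (!ok)
            stop("could not place a collision-free background site for ",
                 kmer, " on ", chrom, " after ", max_attempts,
                 " attempts; increase n_raw")
        }
        rows[[i]] <- cand[sel, , drop = FALSE]
      }
      rep_sites <- do.call(rbind, rows)
      rep_sites$replicate <- r
      reps[[r]] <- rep_sites
    }
    do.call(rbind, reps)
  }
  sites <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  sites <- sites[order(sites$replicate, sites$chrom, sites$start), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  structure(
    list(sites = sites, n_replicates = n_replicates,
         native_composition = comp,
         model = pool$model, n_raw = pool$n_raw),
    class = "background_ensemble"
  )
}

#' @export
print.background_ensemble <- function(x, ...) {
  cat("background_ensemble (", x$model, "): ", x$n_replicates,
      " composition-corrected replicates, ",
      nrow(x$sites) / x$n_replicates, " sites each\n", sep = "")
  invisible(x)
}
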