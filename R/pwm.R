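#' Position weight matrix for Ci/Gli site scoring
#'
#' Constructs a position weight matrix (PWM) object from a matrix of
#' per-position base counts or relative frequencies. The constructor
#' normalizes counts to frequencies, computes the consensus index vector
#' (CIV, a 0--100 measure of per-position base preference), selects the
#' contiguous run of informative core positions used for scoring, and
#' derives the consensus sequence over those core positions.
#'
#' The CIV value of a position is 0 when all four bases are equally
#' preferred and 100 when a single base is strictly preferred; positions
#' whose CIV exceeds `civ_min` (default 70) form the scoring core. For the
#' Ci binding matrix the core is the first nine of eleven positions and the
#' core consensus is `GACCACCCA`.
#'
#' @param freq numeric matrix with one row per motif position and four
#'   columns (A, C, G, T order); entries are counts or relative frequencies.
#' @param name identifier for the matrix.
#' @param civ_min CIV threshold above which a position is considered
#'   informative (core selection).
#' @param alphabet_size alphabet size `K` used in the CIV normalization
#'   `(100/ln K) * sum(f * ln(K f))`; 4 (default) anchors uniform rows at 0,
#'   the 5-letter (gap-inclusive) variant is available as `alphabet_size = 5`.
#' @return an object of class `ci_pwm`: a list with elements `name`, `freq`
#'   (L x 4 frequency matrix), `civ` (length-L numeric), `core` (integer
#'   indices of core positions) and `consensus` (string over core positions).
#' @seealso [read_pwm()], [mss_score()], [enumerate_vocabulary()]
#' @export
#' @examples
#' m <- matrix(rep(c(3, 1, 1, 1), 5), ncol = 4, byrow = TRUE)
#' p <- pwm(m, name = "toy", civ_min = 5)
#' p$consensus
pwm <- function(freq, name = "pwm", civ_min = 70, alphabet_size = 4) {
  freq <- as.matrix(freq)
  if (ncol(freq) != 4L)
    stop("PWM must have 4 columns (A, C, G, T); got ", ncol(freq))
  if (nrow(freq) < 1L) stop("PWM must have at least one position")
  if (any(!is.finite(freq)) || any(freq < 0))
    stop("PWM entries must be finite and non-negative")
  rs <- rowSums(freq)
  if (any(rs == 0))
    stop("all-zero PWM position(s): ", paste(which(rs == 0), collapse = ", "))
  freq <- freq / rs
  dimnames(freq) <- list(NULL, DNA_BASES)

  civ <- compute_civ(freq, alphabet_size = alphabet_size)
  core <- select_core_positions(civ, civ_min = civ_min)
  consensus <- consensus_string(freq[core, , drop = FALSE])

  structure(
    list(name = name, freq = freq, civ = civ, core = core,
         consensus = consensus, civ_min = civ_min,
         alphabet_size = alphabet_size),
    class = "ci_pwm"
  )
}

# per-position argmax base; ties broken alphabetically (and reported)
consensus_string <- function(freq) {
  picks <- apply(freq, 1L, function(row) {
    top <- which(row == max(row))
    if (length(top) > 1L)
      message("consensus tie at a position; choosing alphabetically first of ",
              paste(DNA_BASES[top], collapse = "/"))
    top[1L]
  })
  paste(DNA_BASES[picks], collapse = "")
}

#' Consensus index vector of a PWM
#'
#' Per-position nucleotide-preference strength:
#' `civ(i) = (100 / ln K) * sum_b f(i, b) * ln(K * f(i, b))` with
#' `0 * ln 0 := 0`. With the default `K = 4` a uniform position scores 0 and
#' a single-base position scores 100, and the value increases strictly as a
#' row moves from uniform toward degenerate.
#'
#' @param freq an `ci_pwm` object or an L x 4 row-stochastic matrix.
#' @param alphabet_size normalization constant `K` (4 or 5).
#' @return numeric vector of CIV values, one per position.
#' @export
compute_civ <- function(freq, alphabet_size = 4) {
  if (inherits(freq, "ci_pwm")) freq <- freq$freq
  freq <- as.matrix(freq)
  rs <- rowSums(freq)
  if (any(abs(rs - 1) > 1e-6))
    stop("frequency rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  k <- alphabet_size
  apply(freq, 1L, function(f) {
    nz <- f > 0
    (100 / log(k)) * sum(f[nz] * log(k * f[nz]))
  })
}

#' Select the informative core positions of a PWM
#'
#' Returns the leftmost maximal contiguous run of positions whose CIV value
#' exceeds `civ_min`. The length of this run is the scan width used for
#' site detection (9 for the Ci matrix).
#'
#' @param civ an `ci_pwm` object or a numeric CIV vector.
#' @param civ_min threshold; positions with `civ > civ_min` qualify.
#' @return integer vector of contiguous ascending position indices.
#' @export
select_core_positions <- function(civ, civ_min = 70) {
  if (inherits(civ, "ci_pwm")) civ <- civ$civ
  ok <- civ > civ_min
  if (!any(ok))
    stop("no informative core: no position has CIV > ", civ_min)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])] # leftmost maximal run
  seq.int(starts[best], ends[best])
}

#' Matrix similarity score of a sequence against a PWM
#'
#' The MSS of a core-width sequence is the ratio of its CIV-weighted
#' matrix-vector product to that of the consensus site:
#' `MSS = sum_i civ(i) f(i, seq_i) / sum_i civ(i) f(i, cons_i)` over the
#' core positions. The consensus scores exactly 1 and all values lie in
#' \[0, 1\]. Scores are invariant to rescaling the CIV weights by a positive
#' constant.
#'
#' @param seq character vector of sequences, each of the core width, over
#'   A/C/G/T (no N; callers must pre-filter ambiguous windows).
#' @param pwm an `ci_pwm` object.
#' @return numeric vector of MSS values in \[0, 1\].
#' @export
#' @examples
#' p <- make_toy_matrix("GACCACCCA", sharpness = 0.7)
#' mss_score("GACCACCCA", p)
mss_score <- function(seq, pwm) {
  stopifnot(inherits(pwm, "ci_pwm"))
  w <- pwm$civ[pwm$core]
  fc <- pwm$freq[pwm$core, , drop = FALSE]
  k <- length(pwm$core)
  cons_idx <- match(strsplit(pwm$consensus, "")[[1L]], DNA_BASES)
  denom <- sum(w * fc[cbind(seq_len(k), cons_idx)])
  vapply(seq, function(s) {
    if (nchar(s) != k)
      stop("sequence length ", nchar(s), " != core width ", k)
    idx <- match(strsplit(toupper(s), "")[[1L]], DNA_BASES)
    if (anyNA(idx))
      stop("sequence contains non-ACGT characters: ", s)
    sum(w * fc[cbind(seq_len(k), idx)]) / denom
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Enumerate the thresholded k-mer site vocabulary of a PWM
#'
#' Enumerates all `4^w` sequences of the core width `w`, keeps those with
#' `MSS >= min_mss` that also satisfy the concordance rule (identical C/C or
#' G/G bases at the configured core positions, default 4 and 6 -- positions
#' critical for Ci binding), and pairs every retained sense k-mer with its
#' exact reverse complement. Antisense k-mers inherit the MSS of their sense
#' partner.
#'
#' @param pwm an `ci_pwm` object.
#' @param min_mss minimum matrix similarity score (default 0.75).
#' @param concordance_positions integer pair of 1-based core positions that
#'   must carry identical concordant bases, or `NULL` to disable the rule.
#' @param concordance_bases allowed concordant bases (default C and G).
#' @param max_width refuse enumeration beyond this core width (4^w blow-up).
#' @return an object of class `site_vocabulary`: list with `table` (data
#'   frame of columns `kmer`, `strand`, `sense_kmer`, `mss` covering both
#'   orientations), `sense` (named numeric MSS vector of sense k-mers),
#'   `width`, `min_mss`, and the concordance settings.
#' @export
enumerate_vocabulary <- function(pwm, min_mss = 0.75,
                                 concordance_positions = c(4L, 6L),
                                 concordance_bases = c("C", "G"),
                                 max_width = 12L) {
  stopifnot(inherits(pwm, "ci_pwm"))
  if (min_mss < 0 || min_mss > 1) stop("min_mss must lie in [0, 1]")
  w <- length(pwm$core)
  if (w > max_width)
    stop("core width ", w, " exceeds enumeration cap ", max_width,
         " (4^w k-mers); raise max_width deliberately if intended")
  n <- 4L^w
  idx0 <- 0:(n - 1)

  # digit j in 1..4 indexes the base at position j
  digits <- matrix(0L, nrow = n, ncol = w)
  for (j in seq_len(w))
    digits[, j] <- ((idx0 %/% 4^(w - j)) %% 4) + 1L

  weights <- pwm$civ[pwm$core]
  fc <- pwm$freq[pwm$core, , drop = FALSE]
  cons_idx <- match(strsplit(pwm$consensus, "")[[1L]], DNA_BASES)
  denom <- sum(weights * fc[cbind(seq_len(w), cons_idx)])
  num <- numeric(n)
  for (j in seq_len(w))
    num <- num + (weights[j] * fc[j, ])[digits[, j]]
  mss <- num / denom

  keep <- mss >= min_mss
  if (!is.null(concordance_positions)) {
    stopifnot(length(concordance_positions) == 2L,
              all(concordance_positions >= 1L),
              all(concordance_positions <= w))
    p1 <- digits[, concordance_positions[1L]]
    p2 <- digits[, concordance_positions[2L]]
    conc_idx <- match(toupper(concordance_bases), DNA_BASES)
    keep <- keep & (p1 == p2) & (p1 %in% conc_idx)
  }

  kd <- digits[keep, , drop = FALSE]
  sense_kmers <- apply(kd, 1L, function(d) paste(DNA_BASES[d], collapse = ""))
  sense_mss <- mss[keep]
  if (length(sense_kmers)) {
    o <- order(sense_kmers)
    sense_kmers <- sense_kmers[o]
    sense_mss <- sense_mss[o]
  }
  anti_kmers <- reverse_complement(sense_kmers)
  self_rc <- sense_kmers == anti_kmers
  if (any(self_rc))
    message(sum(self_rc), " k-mer(s) equal their own reverse complement; ",
            "antisense set smaller than sense set")

  tab <- data.frame(
    kmer = c(sense_kmers, anti_kmers[!self_rc]),
    strand = c(rep("+", length(sense_kmers)), rep("-", sum(!self_rc))),
    sense_kmer = c(sense_kmers, sense_kmers[!self_rc]),
    mss = c(sense_mss, sense_mss[!self_rc]),
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab,
         sense = stats::setNames(sense_mss, sense_kmers),
         width = w, min_mss = min_mss,
         concordance_positions = concordance_positions,
         concordance_bases = concordance_bases,
         name = pwm$name,
         cache = new.env(parent = emptyenv())),
    class = "site_vocabulary"
  )
}

#' @export
print.ci_pwm <- function(x, ...) {
  cat("ci_pwm '", x$name, "': ", nrow(x$freq), " positions, core ",
      min(x$core), "-", max(x$core), " (width ", length(x$core),
      "), consensus ", x$consensus, "\n", sep = "")
  invisible(x)
}

#' @export
print.site_vocabulary <- function(x, ...) {
  cat("site_vocabulary '", x$name, "': ", length(x$sense),
      " sense ", x$width, "-mers (", nrow(x$table),
      " with antisense) at MSS >= ", x$min_mss, "\n", sep = "")
  invisible(x)
}

#' Write a site vocabulary to TSV
#'
#' Columns: `kmer`, `strand_class` (+ for sense, - for antisense), `mss`.
#'
#' @param vocab a `site_vocabulary`.
#' @param path output file path.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "site_vocabulary"))
  out <- data.frame(kmer = vocab$table$kmer,
                    strand_class = vocab$table$strand,
                    mss = vocab$table$mss)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
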