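# Independent brute-force oracles and shared fixtures. The oracles
# deliberately use naive string/loop implementations so they share no code
# path with the package internals they check.

# -- reverse complement, character by character ------------------------------
rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1L]]),
        collapse = "")
}

# -- per-k-mer MSS by direct evaluation of the ratio formula -----------------
brute_mss <- function(km, p) {
  w <- length(p$core)
  weights <- p$civ[p$core]
  fc <- p$freq[p$core, , drop = FALSE]
  colnames(fc) <- c("A", "C", "G", "T")
  cons <- strsplit(p$consensus, "")[[1L]]
  den <- 0
  for (j in seq_len(w)) den <- den + weights[j] * fc[j, cons[j]]
  ch <- strsplit(km, "")[[1L]]
  num <- 0
  for (j in seq_len(w)) num <- num + weights[j] * fc[j, ch[j]]
  num / den
}

# -- vocabulary by exhaustive enumeration ------------------------------------
brute_vocabulary <- function(p, min_mss, conc_pos = c(4L, 6L),
                             conc_bases = c("C", "G")) {
  w <- length(p$core)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), w), stringsAsFactors = FALSE))
  kmers <- do.call(paste0, grid)
  mss <- vapply(kmers, brute_mss, numeric(1L), p = p)
  ok <- mss >= min_mss
  if (!is.null(conc_pos)) {
    c1 <- substr(kmers, conc_pos[1L], conc_pos[1L])
    c2 <- substr(kmers, conc_pos[2L], conc_pos[2L])
    ok <- ok & (c1 == c2) & (c1 %in% conc_bases)
  }
  out <- mss[ok]
  names(out) <- kmers[ok]
  out[order(names(out))]
}

# -- genome scan by sliding substring lookup ---------------------------------
brute_scan <- function(genome, vocab) {
  sense <- vocab$sense
  anti <- stats::setNames(sense, vapply(names(sense), rc_chr, character(1L)))
  w <- vocab$width
  rows <- list()
  for (chrom in names(genome$seqs)) {
    s <- toupper(genome$seqs[[chrom]])
    L <- nchar(s)
    if (L < w) next
    for (i in seq_len(L - w + 1L)) {
      sub <- substr(s, i, i + w - 1L)
      if (grepl("[^ACGT]", sub)) next
      hit_plus <- sub %in% names(sense)
      hit_minus <- sub %in% names(anti)
      if (!hit_plus && !hit_minus) next
      if (hit_plus && hit_minus) {
        # dedup rule: higher MSS wins, '+' on ties
        if (anti[[sub]] > sense[[sub]]) {
          strand <- "-"; kmer <- rc_chr(sub); mss <- anti[[sub]]
        } else {
          strand <- "+"; kmer <- sub; mss <- sense[[sub]]
        }
      } else if (hit_plus) {
        strand <- "+"; kmer <- sub; mss <- sense[[sub]]
      } else {
        strand <- "-"; kmer <- rc_chr(sub); mss <- anti[[sub]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = i - 1L, end = i - 1L + w, strand = strand,
        kmer = kmer, mss = mss, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      kmer = character(0), mss = numeric(0))
  rownames(out) <- NULL
  out
}

# -- full cluster chain (enumerate + CC + filters + merge), naive ------------
brute_cluster_chain <- function(sites, bg_replicates, exons, repeats, cfg,
                                expected_floor) {
  sites <- sites[order(sites$chrom, sites$start, sites$end), , drop = FALSE]
  overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  site_hits_set <- function(i, set) {
    if (is.null(set) || !nrow(set)) return(FALSE)
    any(vapply(seq_len(nrow(set)), function(t)
      set$chrom[t] == sites$chrom[i] &&
        overlaps(sites$start[i], sites$end[i], set$start[t], set$end[t]),
      logical(1L)))
  }
  wins <- list()
  for (chrom in unique(sites$chrom)) {
    idx <- which(sites$chrom == chrom)
    n <- length(idx)
    for (k in cfg$min_sites:cfg$max_sites) {
      if (k > n) next
      for (i in 1:(n - k + 1L)) {
        members <- idx[i:(i + k - 1L)]
        start <- sites$start[members[1L]]
        end <- sites$end[members[k]]
        if (end - start > cfg$max_span) next
        # union of site bases
        cov <- rep(FALSE, end - start)
        for (m in members)
          cov[(sites$start[m] - start + 1L):(sites$end[m] - start)] <- TRUE
        # expected count: mean containment over replicates
        cnt <- vapply(bg_replicates, function(b) {
          if (!nrow(b)) return(0L)
          sum(b$chrom == chrom & b$start >= start & b$end <= end)
        }, integer(1L))
        expected <- mean(cnt)
        cc <- k / max(expected, expected_floor)
        excl <- any(vapply(members, site_hits_set, logical(1L), set = exons)) ||
          any(vapply(members, site_hits_set, logical(1L), set = repeats))
        wins[[length(wins) + 1L]] <- list(
          chrom = chrom, start = start, end = end, n_sites = k,
          members = members, avg_mss = mean(sites$mss[members]),
          max_mss = max(sites$mss[members]),
          site_fraction = sum(cov) / (end - start),
          expected = expected, cc = cc,
          pass = cc >= cfg$cc_min &&
            max(sites$mss[members]) >= cfg$anchor_mss && !excl &&
            sum(cov) / (end - start) <= cfg$site_fraction_max)
      }
    }
  }
  passing <- Filter(function(w) w$pass, wins)
  # merge by shared members (repeated pairwise union)
  groups <- lapply(passing, function(w) list(w))
  changed <- TRUE
  while (changed && length(groups) > 1L) {
    changed <- FALSE
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        ma <- unique(unlist(lapply(groups[[a]], `[[`, "members")))
        mb <- unique(unlist(lapply(groups[[b]], `[[`, "members")))
        ca <- groups[[a]][[1L]]$chrom
        cb <- groups[[b]][[1L]]$chrom
        if (ca == cb && length(intersect(ma, mb))) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          groups[[b]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  reported <- lapply(groups, function(g) {
    o <- order(-vapply(g, `[[`, numeric(1L), "n_sites"),
               -vapply(g, `[[`, numeric(1L), "avg_mss"),
               vapply(g, `[[`, numeric(1L), "start"))
    g[[o[1L]]]
  })
  df <- do.call(rbind, lapply(reported, function(w)
    data.frame(chrom = w$chrom, start = w$start, end = w$end,
               n_sites = w$n_sites, avg_mss = w$avg_mss, cc = w$cc)))
  if (is.null(df))
    df <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), n_sites = integer(0),
                     avg_mss = numeric(0), cc = numeric(0))
  df[order(df$chrom, df$start), , drop = FALSE]
}

# -- hand-built background ensemble for unit tests ---------------------------
fake_ensemble <- function(replicate_sites, chroms = NULL) {
  stopifnot(is.list(replicate_sites))
  sites <- do.call(rbind, lapply(seq_along(replicate_sites), function(r) {
    b <- replicate_sites[[r]]
    b$replicate <- rep(as.integer(r), nrow(b))
    b
  }))
  if (is.null(sites))
    sites <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), replicate = integer(0))
  chroms <- chroms %||% unique(sites$chrom)
  structure(
    list(sites = sites, n_replicates = length(replicate_sites),
         native_composition = data.frame(chrom = chroms,
                                         kmer = "XXXXXXXXX", count = 0L),
         model = "manual", n_raw = NA_integer_),
    class = "background_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_sites_fixture <- function(n, chrom = "chrT", chrom_len = 5000L,
                                 width = 9L) {
  starts <- sort(sample.int(chrom_len - width, n))
  # drop overlaps to keep distinct intervals plausible but allow closeness
  data.frame(chrom = chrom, start = starts, end = starts + width,
             strand = sample(c("+", "-"), n, replace = TRUE),
             kmer = "GACCACCCA",
             mss = round(stats::runif(n, 0.75, 1), 3L),
             stringsAsFactors = FALSE)
}

# -- shared heavyweight fixtures, built once per test run --------------------
.shared <- new.env(parent = emptyenv())

toy_pwm <- function() {
  if (is.null(.shared$pwm))
    .shared$pwm <- make_toy_matrix("GACCACCCA", sharpness = 0.95)
  .shared$pwm
}

toy_vocab <- function() {
  if (is.null(.shared$vocab))
    .shared$vocab <- enumerate_vocabulary(toy_pwm(), min_mss = 0.75)
  .shared$vocab
}

# scrubbed 100 kb genome with one planted 5-site consensus cluster
planted_fixture <- function() {
  if (is.null(.shared$planted)) {
    planted <- plan_cluster_sites("chrS", 50000L, 800L,
                                  rep("GACCACCCA", 5L))
    .shared$planted <- list(
      sim = simulate_genome(c(chrS = 100000L), gc = 0.45, planted = planted,
                            vocab = toy_vocab(), scrub = TRUE, seed = 4242),
      planted = planted)
  }
  .shared$planted
}
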