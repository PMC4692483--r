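#' Cluster detection parameters
#'
#' Bundle of the thresholds defining a homotypic site cluster and the
#' filter cascade: clusters carry 3--10 sites within a maximum end-to-end
#' span of 1000 bp (span measured between the outside ends of the flanking
#' sites, boundary inclusive), must be enriched at least `cc_min`-fold over
#' the background expectation, must contain at least one anchor site with
#' `MSS >= anchor_mss`, must not have any member site overlapping an exon
#' or repeat interval, and the member sites themselves may cover at most
#' `site_fraction_max` of the cluster span (clusters denser than that are
#' overwhelmingly repetitive sequence).
#'
#' @param min_sites,max_sites cluster size bounds (default 3 and 10).
#' @param max_span maximum end-to-end span in bp (default 1000, inclusive).
#' @param cc_min minimum clustering coefficient (default 4).
#' @param anchor_mss minimum best-site MSS (default 0.81).
#' @param site_fraction_max maximum fraction of the span covered by site
#'   bases, overlapping bases counted once (default 0.25).
#' @param expected_floor floor for the expected count in the clustering
#'   coefficient; `NULL` (default) means `1/n_replicates` of the ensemble.
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(min_sites = 3L, max_sites = 10L, max_span = 1000L,
                           cc_min = 4, anchor_mss = 0.81,
                           site_fraction_max = 0.25, expected_floor = NULL) {
  if (min_sites < 2L) stop("min_sites must be >= 2")
  if (min_sites > max_sites) stop("min_sites must not exceed max_sites")
  if (max_span <= 0L) stop("max_span must be positive")
  if (cc_min <= 0) stop("cc_min must be positive")
  structure(list(min_sites = as.integer(min_sites),
                 max_sites = as.integer(max_sites),
                 max_span = as.integer(max_span),
                 cc_min = cc_min, anchor_mss = anchor_mss,
                 site_fraction_max = site_fraction_max,
                 expected_floor = expected_floor),
            class = "cluster_config")
}

# union width of sorted-by-start intervals i..j
union_width <- function(starts, ends, i, j) {
  tot <- 0L
  cur_s <- starts[i]
  cur_e <- ends[i]
  if (j > i) for (t in (i + 1L):j) {
    if (starts[t] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- starts[t]
      cur_e <- ends[t]
    } else {
      cur_e <- max(cur_e, ends[t])
    }
  }
  tot + (cur_e - cur_s)
}

#' Enumerate candidate cluster windows
#'
#' For each cluster size k in `[min_sites, max_sites]`, every window of k
#' consecutive sites (per chromosome, in coordinate order) whose span from
#' the first site's start to the last site's end is at most `max_span` is
#' emitted once.
#'
#' @param sites binding-site data frame sorted by (chrom, start); the
#'   returned window site indices refer to rows of this input.
#' @param config a [cluster_config()].
#' @return data frame of candidate windows: `chrom`, `start`, `end`
#'   (outside ends, 0-based half-open), `n_sites`, `span`, `avg_mss`,
#'   `max_mss`, `site_bp` (union of site bases), `site_fraction`,
#'   `first_site`, `last_site` (row indices into `sites`).
#' @export
enumerate_windows <- function(sites, config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  if (!is_sorted_intervals(sites))
    stop("sites must be sorted by (chrom, start); see sort_intervals order")
  out <- list()
  for (chrom in unique(sites$chrom)) {
    idx <- which(sites$chrom == chrom)
    n <- length(idx)
    s <- sites$start[idx]
    e <- sites$end[idx]
    mss <- sites$mss[idx]
    cmss <- c(0, cumsum(mss))
    for (k in config$min_sites:config$max_sites) {
      if (k > n) break
      i <- seq_len(n - k + 1L)
      j <- i + k - 1L
      span <- e[j] - s[i]
      keep <- which(span <= config$max_span)
      if (!length(keep)) next
      sbp <- vapply(keep, function(t) union_width(s, e, t, t + k - 1L),
                    integer(1L))
      mmax <- vapply(keep, function(t) max(mss[t:(t + k - 1L)]), numeric(1L))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = s[keep],
        end = e[keep + k - 1L],
        n_sites = k,
        span = span[keep],
        avg_mss = (cmss[keep + k] - cmss[keep]) / k,
        max_mss = mmax,
        site_bp = sbp,
        site_fraction = sbp / span[keep],
        first_site = idx[keep],
        last_site = idx[keep + k - 1L],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      span = integer(0), avg_mss = numeric(0),
                      max_mss = numeric(0), site_bp = integer(0),
                      site_fraction = numeric(0), first_site = integer(0),
                      last_site = integer(0))
  res <- res[order(res$chrom, res$start, res$end, res$n_sites), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Expected background site count within regions
#'
#' Mean, over the replicates of a composition-corrected background
#' ensemble, of the number of background sites whose interval lies fully
#' within each query region. Deterministic for a fixed ensemble.
#'
#' @param regions data frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. windows from [enumerate_windows()].
#' @param ensemble a `background_ensemble`.
#' @return numeric vector of expected counts, one per region.
#' @export
expected_site_count <- function(regions, ensemble) {
  stopifnot(inherits(ensemble, "background_ensemble"))
  covered <- unique(ensemble$native_composition$chrom)
  missing <- setdiff(unique(regions$chrom), covered)
  if (length(missing))
    stop("regions on chromosome(s) not covered by the ensemble: ",
         paste(missing, collapse = ", "))
  if (!nrow(regions)) return(numeric(0))
  bg <- as_granges0(ensemble$sites)
  q <- as_granges0(regions)
  hits <- GenomicRanges::findOverlaps(bg, q, type = "within")
  tabulate(S4Vectors::subjectHits(hits), nbins = nrow(regions)) /
    ensemble$n_replicates
}

#' Clustering coefficient
#'
#' Ratio of the observed site count in a native-genome region to the
#' average count in the same region across the background replicates. A
#' zero (or tiny) expectation is floored at `expected_floor` -- by default
#' one site in one replicate, i.e. `1/n_replicates` -- so the coefficient
#' stays finite and monotone.
#'
#' @param observed observed site count(s).
#' @param expected expected count(s) from [expected_site_count()].
#' @param expected_floor denominator floor (supply `1/n_replicates`).
#' @return numeric vector of clustering coefficients.
#' @export
#' @examples
#' cluster_coefficient(4, 1)          # 4
#' cluster_coefficient(3, 0, 1/100)   # 300
cluster_coefficient <- function(observed, expected, expected_floor = 0.01) {
  stopifnot(all(observed >= 0), all(expected >= 0), expected_floor > 0)
  observed / pmax(expected, expected_floor)
}

#' Apply the cluster filter cascade
#'
#' Flags each candidate window on the four cluster filters: clustering
#' coefficient at least `cc_min`, best member site at least `anchor_mss`,
#' no member site overlapping an exon or repeat interval by 1 bp or more,
#' and member-site bases covering at most `site_fraction_max` of the span.
#' Failed windows are retained with their failure flags; `pass` is the
#' conjunction (the flag evaluation order is for readability only).
#'
#' @param windows window data frame from [enumerate_windows()] carrying a
#'   `cc` column (see [cluster_coefficient()]).
#' @param sites the site data frame the windows were enumerated from.
#' @param exons,repeats optional interval data frames (`chrom`, `start`,
#'   `end`, 0-based half-open); `NULL` disables that exclusion.
#' @param config a [cluster_config()].
#' @return `windows` with added logical columns `cc_pass`, `anchor_pass`,
#'   `exon_clear`, `repeat_clear`, `fraction_pass`, `pass`.
#' @export
apply_filters <- function(windows, sites, exons = NULL, repeats = NULL,
                          config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  if (nrow(windows) && is.null(windows$cc))
    stop("windows lack a 'cc' column; compute the clustering coefficient ",
         "first (expected_site_count + cluster_coefficient)")
  site_in <- function(set) {
    if (is.null(set) || !nrow(set)) return(rep(FALSE, nrow(sites)))
    exclusion_overlap(sites, set)
  }
  excl_exon <- site_in(exons)
  excl_rep <- site_in(repeats)
  win_any <- function(flag) {
    vapply(seq_len(nrow(windows)), function(i)
      any(flag[windows$first_site[i]:windows$last_site[i]]), logical(1L))
  }
  windows$cc_pass <- windows$cc >= config$cc_min
  windows$anchor_pass <- windows$max_mss >= config$anchor_mss
  windows$exon_clear <- if (nrow(windows)) !win_any(excl_exon) else logical(0)
  windows$repeat_clear <- if (nrow(windows)) !win_any(excl_rep) else logical(0)
  windows$fraction_pass <- windows$site_fraction <= config$site_fraction_max
  windows$pass <- windows$cc_pass & windows$anchor_pass &
    windows$exon_clear & windows$repeat_clear & windows$fraction_pass
  windows
}

#' Merge overlapping passing windows into reported clusters
#'
#' Passing windows that share at least one member site are grouped; each
#' group is reported as its window with the most sites, ties broken by
#' higher average MSS, then leftmost start. Groups with disjoint site sets
#' remain separate clusters, so adjacent clusters separated by a span gap
#' stay distinct. All candidate windows remain available in the verbose
#' window table; merging only selects the reported representative.
#'
#' @param windows filtered window data frame ([apply_filters()]); only rows
#'   with `pass == TRUE` participate.
#' @return data frame of reported clusters (same columns plus `cluster_id`
#'   and `n_windows`, the group size).
#' @export
merge_and_report <- function(windows) {
  w <- windows[windows$pass %||% rep(TRUE, nrow(windows)), , drop = FALSE]
  if (!nrow(w)) {
    w$cluster_id <- integer(0)
    w$n_windows <- integer(0)
    return(w)
  }
  out <- list()
  gid <- 0L
  for (chrom in unique(w$chrom)) {
    wc <- w[w$chrom == chrom, , drop = FALSE]
    o <- order(wc$first_site, wc$last_site)
    wc <- wc[o, , drop = FALSE]
    comp <- integer(nrow(wc))
    cur <- 0L
    cur_max <- -Inf
    for (i in seq_len(nrow(wc))) {
      if (wc$first_site[i] > cur_max) cur <- cur + 1L # no shared site
      comp[i] <- cur
      cur_max <- max(cur_max, wc$last_site[i])
    }
    for (g in unique(comp)) {
      grp <- wc[comp == g, , drop = FALSE]
      pick <- grp[order(-grp$n_sites, -grp$avg_mss, grp$start), ,
                  drop = FALSE][1L, , drop = FALSE]
      gid <- gid + 1L
      pick$cluster_id <- gid
      pick$n_windows <- nrow(grp)
      out[[gid]] <- pick
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$cluster_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Rank reported clusters
#'
#' Descending average MSS (to favor clusters whose sites are all plausibly
#' bound), ties broken by descending site count, then coordinate order.
#'
#' @param clusters cluster data frame.
#' @return the same data frame in ranked order with a `rank` column.
#' @export
rank_clusters <- function(clusters) {
  o <- order(-clusters$avg_mss, -clusters$n_sites, clusters$chrom,
             clusters$start)
  res <- clusters[o, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Human-readable cluster report table
#'
#' Display coordinates are 1-based inclusive (UCSC style); average MSS is
#' rounded to 3 decimals. The per-site sub-table lists the member sites of
#' each cluster.
#'
#' @param clusters ranked cluster data frame ([rank_clusters()]).
#' @param sites the site data frame the windows were enumerated from.
#' @return list with `clusters` (display table) and `sites` (per-cluster
#'   member-site table).
#' @export
cluster_report <- function(clusters, sites) {
  disp <- data.frame(
    rank = clusters$rank %||% seq_len(nrow(clusters)),
    region = sprintf("%s:%d-%d", clusters$chrom, clusters$start + 1L,
                     clusters$end),
    chrom = clusters$chrom,
    display_start = clusters$start + 1L,
    display_end = clusters$end,
    n_sites = clusters$n_sites,
    avg_mss = round(clusters$avg_mss, 3L),
    max_mss = clusters$max_mss,
    cc = clusters$cc %||% NA_real_,
    stringsAsFactors = FALSE
  )
  mem <- lapply(seq_len(nrow(clusters)), function(i) {
    s <- sites[clusters$first_site[i]:clusters$last_site[i], , drop = FALSE]
    s$cluster_rank <- disp$rank[i]
    s
  })
  mem <- if (length(mem)) do.call(rbind, mem) else
    sites[integer(0), , drop = FALSE]
  list(clusters = disp, sites = mem)
}
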