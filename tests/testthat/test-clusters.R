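mk_sites <- function(starts, mss = 0.9, chrom = "c1", width = 9L,
                     kmer = "GACCACCCA") {
  n <- length(starts)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(starts),
             end = as.integer(starts) + width, strand = rep_len("+", n),
             kmer = rep_len(kmer, n), mss = rep_len(mss, n),
             stringsAsFactors = FALSE)
}

test_that("window span boundary is inclusive at max_span", {
  cfg <- cluster_config()
  w <- enumerate_windows(mk_sites(c(0, 500, 991)), cfg) # span exactly 1000
  expect_equal(nrow(w), 1)
  expect_equal(w$span, 1000)
  expect_equal(w$start, 0)
  expect_equal(w$end, 1000)
  expect_equal(nrow(enumerate_windows(mk_sites(c(0, 500, 992)), cfg)), 0)
  expect_equal(nrow(enumerate_windows(mk_sites(c(0, 500)), cfg)), 0)
  expect_error(cluster_config(min_sites = 5, max_sites = 3), "exceed")
})

test_that("window enumeration equals brute force on random fixtures", {
  cfg <- cluster_config()
  set.seed(11)
  for (rep in 1:5) {
    starts <- sort(sample.int(3000, 12))
    s <- mk_sites(starts, mss = runif(12, 0.75, 1))
    w <- enumerate_windows(s, cfg)
    # brute force over all consecutive-site subsets
    want <- 0L
    for (i in 1:12) for (j in i:12) {
      k <- j - i + 1L
      if (k >= 3 && k <= 10 && s$end[j] - s$start[i] <= 1000) {
        want <- want + 1L
        row <- w[w$first_site == i & w$last_site == j, ]
        expect_equal(nrow(row), 1)
        expect_equal(row$avg_mss, mean(s$mss[i:j]))
        expect_equal(row$n_sites, k)
      }
    }
    expect_equal(nrow(w), want)
  }
})

test_that("expected counts average full containment over replicates", {
  region <- data.frame(chrom = "c1", start = 100L, end = 1100L)
  inside <- function(n) if (n) mk_sites(seq(200, 200 + 20 * (n - 1), 20)[1:n])
    else mk_sites(integer(0))
  counts <- c(0, 1, 2, 1, 0, 1, 3, 0, 1, 1)
  ens <- fake_ensemble(lapply(counts, inside), chroms = "c1")
  expect_equal(expected_site_count(region, ens), 1.0)
  expect_equal(expected_site_count(region,
                                   fake_ensemble(lapply(rep(1, 4), inside),
                                                 chroms = "c1")), 1.0)
  expect_equal(expected_site_count(region,
                                   fake_ensemble(lapply(rep(0, 4), inside),
                                                 chroms = "c1")), 0.0)
  # containment, not mere overlap: a site straddling the edge is excluded
  straddle <- mk_sites(95) # [95,104) crosses start=100
  ens2 <- fake_ensemble(list(straddle), chroms = "c1")
  expect_equal(expected_site_count(region, ens2), 0)
  expect_error(expected_site_count(data.frame(chrom = "cX", start = 0L,
                                              end = 10L), ens),
               "not covered")
})

test_that("clustering coefficient applies the expected-count floor", {
  expect_equal(cluster_coefficient(4, 1), 4)
  expect_equal(cluster_coefficient(3, 0, expected_floor = 1 / 100), 300)
  expect_equal(cluster_coefficient(0, 5), 0)
  expect_true(cluster_coefficient(4, 1) >= cluster_config()$cc_min)
  expect_error(cluster_coefficient(3, -1), "expected")
})

test_that("CC is monotone in the background site count inside the window", {
  s <- mk_sites(c(0, 300, 600))
  cfg <- cluster_config()
  w <- enumerate_windows(s, cfg)
  ccs <- vapply(0:4, function(nbg) {
    reps <- list(if (nbg) mk_sites(seq(50, 50 + 30 * (nbg - 1),
                                       length.out = nbg)) else
                   mk_sites(integer(0)),
                 mk_sites(integer(0)))
    e <- expected_site_count(w, fake_ensemble(reps, chroms = "c1"))
    cluster_coefficient(w$n_sites, e, 1 / 2)
  }, numeric(1))
  # adding a background site inside the window never increases the CC, and
  # strictly decreases it once the expectation clears the floor
  expect_true(all(diff(ccs) <= 0))
  expect_true(all(diff(ccs[-1]) < 0))
})

test_that("the filter cascade flags each failure mode independently", {
  cfg <- cluster_config()
  # 3 x 9 bp sites in a 100 bp span: fraction 0.27 > 0.25
  dense <- mk_sites(c(0, 50, 91))
  w <- enumerate_windows(dense, cfg)
  expect_equal(w$site_fraction, 0.27)
  w$cc <- 10
  w <- apply_filters(w, dense, config = cfg)
  expect_false(w$fraction_pass)
  expect_false(w$pass)
  expect_true(w$cc_pass && w$anchor_pass && w$exon_clear && w$repeat_clear)

  # best site MSS 0.80 fails the 0.81 anchor rule
  weak <- mk_sites(c(0, 300, 600), mss = c(0.78, 0.80, 0.79))
  w2 <- enumerate_windows(weak, cfg)
  w2$cc <- 10
  w2 <- apply_filters(w2, weak, config = cfg)
  expect_false(w2$anchor_pass)
  # raising one site to 0.81 rescues it
  weak$mss[2] <- 0.81
  w3 <- enumerate_windows(weak, cfg)
  w3$cc <- 10
  w3 <- apply_filters(w3, weak, config = cfg)
  expect_true(w3$anchor_pass && w3$pass)

  # 1 bp exon overlap with any member site excludes the window
  s <- mk_sites(c(0, 300, 600))
  w4 <- enumerate_windows(s, cfg)
  w4$cc <- 10
  exon1 <- data.frame(chrom = "c1", start = 8L, end = 30L) # overlaps [0,9)
  exon0 <- data.frame(chrom = "c1", start = 9L, end = 30L) # abuts only
  expect_false(apply_filters(w4, s, exons = exon1, config = cfg)$exon_clear)
  expect_true(apply_filters(w4, s, exons = exon0, config = cfg)$exon_clear)
  expect_false(apply_filters(w4, s, repeats = exon1,
                             config = cfg)$repeat_clear)
  expect_error(apply_filters(w4[setdiff(names(w4), "cc")], s, config = cfg),
               "cc")
})

test_that("shared-site windows merge to one representative; disjoint stay", {
  cfg <- cluster_config()
  s <- mk_sites(c(0, 300, 600, 900), mss = c(0.95, 0.9, 0.9, 0.8))
  w <- enumerate_windows(s, cfg) # {1,2,3} and {2,3,4} (4-site span 909 too)
  w$cc <- 10
  w <- apply_filters(w, s, config = cfg)
  w <- w[w$n_sites == 3, ] # keep the two 3-site windows
  m <- merge_and_report(w)
  expect_equal(nrow(m), 1)
  expect_equal(m$first_site, 1) # higher avg_mss wins the tie on n_sites
  expect_equal(m$n_windows, 2)

  far <- rbind(mk_sites(c(0, 300, 600)), mk_sites(c(5000, 5300, 5600)))
  wf <- enumerate_windows(far, cfg)
  wf$cc <- 10
  wf <- apply_filters(wf, far, config = cfg)
  mf <- merge_and_report(wf)
  expect_equal(nrow(mf), 2)
})

test_that("adjacent planted clusters separated by span gaps stay distinct", {
  # three 4-site groups, each within 1000 bp, gaps > 1000 bp between groups
  cfg <- cluster_config()
  groups <- list(seq(0, 900, 300), seq(2200, 3100, 300),
                 seq(4400, 5300, 300))
  s <- mk_sites(unlist(groups))
  w <- enumerate_windows(s, cfg)
  w$cc <- 10
  w <- apply_filters(w, s, config = cfg)
  m <- merge_and_report(w)
  expect_equal(nrow(m), 3)
  expect_equal(m$n_sites, c(4, 4, 4))
  expect_equal(m$start, c(0, 2200, 4400))
})

test_that("ranking sorts by avg MSS, then site count, then coordinate", {
  set.seed(13)
  cl <- data.frame(chrom = sample(c("c1", "c2"), 20, TRUE),
                   start = sample.int(10000, 20),
                   n_sites = sample(3:7, 20, TRUE),
                   avg_mss = round(runif(20, 0.8, 1), 3))
  cl$end <- cl$start + 500L
  ranked <- rank_clusters(cl)
  o <- order(-cl$avg_mss, -cl$n_sites, cl$chrom, cl$start)
  expect_equal(ranked$start, cl$start[o])
  expect_equal(ranked$rank, 1:20)
  # descending avg MSS mirrors a tested-set ordering like 1.000 > 0.941 > 0.903
  tied <- data.frame(chrom = "c1", start = c(900L, 100L, 500L),
                     end = c(1000L, 200L, 600L), n_sites = 3,
                     avg_mss = 0.9)
  expect_equal(rank_clusters(tied)$start, c(100L, 500L, 900L))
})

test_that("the whole chain matches brute force on small site sets", {
  cfg <- cluster_config()
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    starts <- sort(sample(seq(1L, 4000L, 3L), n))
    sites <- mk_sites(starts, mss = round(runif(n, 0.75, 1), 3))
    reps <- lapply(1:4, function(r) {
      nb <- rpois(1, 8)
      if (nb == 0) return(mk_sites(integer(0)))
      mk_sites(sort(sample(seq(2L, 4000L, 3L), nb)))
    })
    exons <- data.frame(chrom = "c1",
                        start = sample.int(4000, 2), end = 0L)
    exons$end <- exons$start + 40L
    repeats <- data.frame(chrom = "c1", start = sample.int(4000, 1),
                          end = 0L)
    repeats$end <- repeats$start + 60L

    ens <- fake_ensemble(reps, chroms = "c1")
    w <- enumerate_windows(sites, cfg)
    w$expected <- expected_site_count(w, ens)
    w$cc <- cluster_coefficient(w$n_sites, w$expected, 1 / 4)
    w <- apply_filters(w, sites, exons = exons, repeats = repeats,
                       config = cfg)
    got <- merge_and_report(w)
    want <- brute_cluster_chain(sites, reps, exons, repeats, cfg,
                                expected_floor = 1 / 4)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_sites, want$n_sites)
      expect_equal(got$cc, want$cc)
    }
  }
})

test_that("cluster report renders 1-based inclusive display coordinates", {
  s <- mk_sites(c(0, 300, 600))
  cfg <- cluster_config()
  w <- enumerate_windows(s, cfg)
  w$cc <- 8
  w <- apply_filters(w, s, config = cfg)
  cl <- rank_clusters(merge_and_report(w))
  rep <- cluster_report(cl, s)
  expect_equal(rep$clusters$region, "c1:1-609")
  expect_equal(rep$clusters$display_start, 1)
  expect_equal(rep$clusters$display_end, 609)
  expect_equal(rep$clusters$avg_mss, 0.9)
  expect_equal(nrow(rep$sites), 3)
})
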