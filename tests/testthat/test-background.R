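test_that("bg_random keeps length and N, homogenizes composition", {
  expect_equal(bg_random("NNNN"), "NNNN")
  set.seed(1)
  seq <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE,
                      prob = c(.4, .1, .1, .4)), collapse = "")
  out <- bg_random(seq)
  expect_equal(nchar(out), 10000)
  # each base frequency within 5 SD of 0.25 (binomial bound)
  counts <- table(factor(strsplit(out, "")[[1]], c("A", "C", "G", "T")))
  sd5 <- 5 * sqrt(0.25 * 0.75 * 10000)
  expect_true(all(abs(counts - 2500) < sd5))
  # determinism under a fixed seed
  set.seed(7); a <- bg_random(seq)
  set.seed(7); b <- bg_random(seq)
  expect_identical(a, b)
})

test_that("bg_shuffle3mer preserves the contiguous 3-mer multiset", {
  set.seed(2)
  out <- bg_shuffle3mer("AAACCCGGG")
  blocks <- substring(out, c(1, 4, 7), c(3, 6, 9))
  expect_setequal(blocks, c("AAA", "CCC", "GGG"))
  expect_equal(bg_shuffle3mer("AAAAAA"), "AAAAAA")

  seq <- paste(sample(c("A", "C", "G", "T"), 9999, replace = TRUE),
               collapse = "")
  out <- bg_shuffle3mer(seq)
  expect_equal(nchar(out), 9999)
  b_in <- sort(substring(seq, seq(1, 9997, 3), seq(3, 9999, 3)))
  b_out <- sort(substring(out, seq(1, 9997, 3), seq(3, 9999, 3)))
  expect_identical(b_in, b_out)
  # mononucleotide composition preserved as a consequence
  expect_identical(sort(strsplit(seq, "")[[1]]), sort(strsplit(out, "")[[1]]))

  # remainder of length 1-2 stays in place
  out10 <- bg_shuffle3mer(substr(seq, 1, 10))
  expect_equal(nchar(out10), 10)
  expect_equal(substr(out10, 10, 10), substr(seq, 10, 10))
})

test_that("bg_flip_gc_at preserves per-position GC identity exactly", {
  set.seed(3)
  expect_true(grepl("^[GC]+$", bg_flip_gc_at("GGCC")))
  expect_true(grepl("^[AT]+$", bg_flip_gc_at("ATAT")))
  expect_equal(bg_flip_gc_at("NNN"), "NNN")
  expect_error(bg_flip_gc_at("ACGX"), "outside A/C/G/T/N")

  seq <- paste(sample(c("A", "C", "G", "T", "N"), 50000, replace = TRUE,
                      prob = c(.3, .2, .2, .29, .01)), collapse = "")
  out <- bg_flip_gc_at(seq)
  expect_equal(nchar(out), 50000)
  # GC/AT skeleton identical => GC content of every window of every width
  skel <- function(x) chartr("ACGTN", "WSSWN", x)
  expect_identical(skel(out), skel(seq))
  # positionwise: output base is input or its complement
  vi <- strsplit(seq, "")[[1]]
  vo <- strsplit(out, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  expect_true(all(vo == vi | vo == comp[vi]))
  # and flips do occur
  expect_gt(mean(vo != vi), 0.4)
})

test_that("flank GC profile handles pure and edge cases", {
  g <- genome_assembly(c(gg = strrep("G", 200), aa = strrep("A", 200)))
  site <- function(chrom) data.frame(chrom = chrom, start = 95L, end = 104L)
  expect_equal(gc_context_profile(site("gg"), g)$per_site$gc, 1)
  expect_equal(gc_context_profile(site("aa"), g)$per_site$gc, 0)
  # site bases are excluded from the flanks
  mixed <- genome_assembly(c(m = paste0(strrep("G", 95), strrep("A", 9),
                                        strrep("G", 96))))
  expect_equal(gc_context_profile(site("m"), mixed)$per_site$gc, 1)
  # sites without a full flank are excluded and counted
  close_site <- data.frame(chrom = "gg", start = 10L, end = 19L)
  pr <- gc_context_profile(rbind(site("gg"), close_site), g)
  expect_equal(nrow(pr$per_site), 1)
  expect_equal(pr$n_excluded, 1)
})

test_that("flip reproduces native flank GC exactly; random homogenizes it", {
  # GC-rich island carrying the sites in an AT-rich genome
  v <- toy_vocab()
  gc_land <- data.frame(chrom = "chrG", start = c(0L, 40000L, 60000L),
                        end = c(40000L, 60000L, 100000L),
                        gc = c(0.3, 0.75, 0.3))
  planted <- plan_cluster_sites("chrG", 45000L, 8000L,
                                rep("GACCACCCA", 10))
  sim <- simulate_genome(c(chrG = 100000L), gc = gc_land, planted = planted,
                         vocab = v, scrub = FALSE, seed = 53)
  native <- gc_context_profile(sim$truth, sim$genome)
  expect_gt(native$mean, 0.6)

  set.seed(54)
  flip_g <- genome_assembly(c(chrG = bg_flip_gc_at(sim$genome$seqs[[1]])))
  flip <- gc_context_profile(sim$truth, flip_g)
  expect_equal(flip$per_site$gc, native$per_site$gc) # exact, by construction

  rand_g <- genome_assembly(c(chrG = bg_random(sim$genome$seqs[[1]])))
  rand <- gc_context_profile(sim$truth, rand_g)
  expect_lt(abs(rand$mean - 0.5), 3 * rand$sem)

  shuf_g <- genome_assembly(c(chrG = bg_shuffle3mer(sim$genome$seqs[[1]])))
  shuf <- gc_context_profile(sim$truth, shuf_g)
  # homogenized toward the genome-wide GC, far below the native context
  sep <- abs(native$mean - shuf$mean) /
    sqrt(native$sem^2 + shuf$sem^2)
  expect_gt(sep, 3)
})

test_that("the site pool recounts its raw replicates exactly", {
  v <- toy_vocab()
  sim <- simulate_genome(c(chrP = 10000L), gc = 0.6, seed = 61)
  pool <- build_site_pool(sim$genome, v, model = "flip_gc_at", n_raw = 10,
                          seed = 62)
  expect_equal(nrow(pool$sites), sum(pool$replicate_counts$n_sites))
  expect_equal(sort(unique(pool$sites$replicate)),
               pool$replicate_counts$replicate[
                 pool$replicate_counts$n_sites > 0])
  # determinism
  pool2 <- build_site_pool(sim$genome, v, model = "flip_gc_at", n_raw = 10,
                           seed = 62)
  expect_equal(pool$sites, pool2$sites)
})

test_that("flip backgrounds of a motif-enriched genome carry fewer sites", {
  v <- toy_vocab()
  # natural GC-0.55 background plus 30 planted consensus sites: the plants
  # are real enrichment the randomization cannot know about
  set.seed(71)
  starts <- sort(sample(seq(100L, 49000L, by = 60L), 30))
  planted <- data.frame(chrom = "chrE", start = starts, kmer = "GACCACCCA",
                        strand = "+")
  sim <- simulate_genome(c(chrE = 50000L), gc = 0.55, planted = planted,
                         vocab = v, scrub = FALSE, seed = 72)
  native_n <- nrow(scan_sites(sim$genome, v))
  pool <- build_site_pool(sim$genome, v, model = "flip_gc_at", n_raw = 30,
                          seed = 73)
  expect_gt(mean(pool$replicate_counts$n_sites < native_n), 0.9)
})

test_that("reconstructed backgrounds match native composition exactly", {
  v <- toy_vocab()
  kmers <- c("GACCACCCA", "AACCACCCA", "GACCACCCT")
  planted <- data.frame(chrom = "chrC",
                        start = c(1000L, 5000L, 9000L, 13000L, 17000L,
                                  21000L),
                        kmer = rep(kmers, 2), strand = "+")
  sim <- simulate_genome(c(chrC = 30000L), gc = 0.5, planted = planted,
                         vocab = v, scrub = TRUE, seed = 81)
  native <- scan_sites(sim$genome, v)
  expect_equal(nrow(native), 6)
  pool <- build_site_pool(sim$genome, v, model = "flip_gc_at", n_raw = 100,
                          seed = 82)
  ens <- suppressWarnings(
    reconstruct_backgrounds(pool, native, n_replicates = 25, seed = 83))
  native_tab <- table(native$kmer)
  for (r in seq_len(25)) {
    rep_sites <- ens$sites[ens$sites$replicate == r, ]
    expect_equal(nrow(rep_sites), 6)
    expect_equal(table(rep_sites$kmer), native_tab)
    expect_false(anyDuplicated(rep_sites$start) > 0)
    expect_true(all(rep_sites$end <= 30000L))
  }
  # deterministic given the seed
  ens2 <- suppressWarnings(
    reconstruct_backgrounds(pool, native, n_replicates = 25, seed = 83))
  expect_equal(ens$sites, ens2$sites)
})

test_that("reconstruction falls back by MSS class or fails informatively", {
  native <- data.frame(chrom = "c1", start = c(10L, 50L), end = c(19L, 59L),
                       strand = "+", kmer = c("AAACACCCA", "AAACACCCA"),
                       mss = 0.78)
  make_pool <- function(sites) {
    structure(list(sites = sites,
                   replicate_counts = data.frame(replicate = 1L,
                                                 n_sites = nrow(sites)),
                   model = "flip_gc_at", n_raw = 1L),
              class = "site_pool")
  }
  # only one distinct position for the native k-mer, but same-MSS-class
  # positions from another k-mer are available
  pool <- make_pool(data.frame(
    chrom = "c1", start = c(100L, 100L, 200L, 300L),
    end = c(109L, 109L, 209L, 309L), strand = "+",
    kmer = c("AAACACCCA", "AAACACCCA", "AACCACCCC", "AACCACCCC"),
    mss = 0.78, replicate = 1L))
  expect_warning(ens <- reconstruct_backgrounds(pool, native,
                                                n_replicates = 5, seed = 1),
                 "MSS class")
  for (r in 1:5) {
    rs <- ens$sites[ens$sites$replicate == r, ]
    expect_equal(rs$kmer, c("AAACACCCA", "AAACACCCA"))
  }
  # not even the MSS class can supply enough distinct positions
  pool2 <- make_pool(data.frame(chrom = "c1", start = 100L, end = 109L,
                                strand = "+", kmer = "AAACACCCA",
                                mss = 0.78, replicate = 1L))
  expect_error(suppressWarnings(
    reconstruct_backgrounds(pool2, native, n_replicates = 2, seed = 1)),
    "increase n_raw")
})
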