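#' Default pipeline configuration
#'
#' All thresholds of the scan / background / cluster stages with their
#' defaults: vocabulary MSS cutoff 0.75 with C/C-or-G/G concordance at core
#' positions 4 and 6, CIV core threshold 70, GC/AT-flip background model
#' with 1000 raw and 100 composition-corrected replicates, and cluster
#' thresholds of 3--10 sites / 1000 bp span / CC >= 4 / anchor MSS >= 0.81
#' / 25% site-length fraction.
#'
#' @param ... overrides for any defaults (unknown names are an error).
#' @return named list of configuration values.
#' @export
pipeline_defaults <- function(...) {
  cfg <- list(
    min_mss = 0.75,
    concordance_positions = c(4L, 6L),
    concordance_bases = c("C", "G"),
    civ_core_min = 70,
    model = "flip_gc_at",
    n_raw = 1000L,
    n_replicates = 100L,
    seed = NULL,
    min_sites = 3L, max_sites = 10L, max_span = 1000L,
    cc_min = 4, anchor_mss = 0.81, site_fraction_max = 0.25,
    merge_duplicates = TRUE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_defaults()]; file paths (`genome`, `matrix`,
#' `refflat`, `exons`, `repeats`, `ctcf`, `lifted`, `out_dir`) are carried
#' through untouched. Thresholds are validated.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  path_keys <- c("genome", "matrix", "refflat", "exons", "repeats",
                 "ctcf", "lifted", "out_dir")
  over <- raw[setdiff(names(raw), path_keys)]
  cfg <- do.call(pipeline_defaults, over)
  cfg[path_keys] <- raw[path_keys]
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$min_mss < 0 || cfg$min_mss > 1)
    stop("min_mss must lie in [0, 1]; got ", cfg$min_mss)
  if (cfg$anchor_mss < 0 || cfg$anchor_mss > 1)
    stop("anchor_mss must lie in [0, 1]")
  if (cfg$n_raw < 1L || cfg$n_replicates < 1L)
    stop("n_raw and n_replicates must be positive")
  cluster_config(cfg$min_sites, cfg$max_sites, cfg$max_span, cfg$cc_min,
                 cfg$anchor_mss, cfg$site_fraction_max) # threshold checks
  invisible(cfg)
}

#' Scan stage: vocabulary construction plus genome scan
#'
#' @param genome a `genome_assembly`.
#' @param pwm an `ci_pwm`.
#' @param config configuration list ([pipeline_defaults()]).
#' @param out_dir optional directory for `sites.bed` and
#'   `site_summary.tsv` (per-chromosome counts).
#' @return list with `vocab`, `sites`, `summary`.
#' @export
run_scan <- function(genome, pwm, config = pipeline_defaults(),
                     out_dir = NULL) {
  validate_config(config)
  vocab <- enumerate_vocabulary(
    pwm, min_mss = config$min_mss,
    concordance_positions = config$concordance_positions,
    concordance_bases = config$concordance_bases)
  message("scan: vocabulary of ", length(vocab$sense), " sense ",
          vocab$width, "-mers (", nrow(vocab$table), " with antisense)")
  sites <- scan_sites(genome, vocab,
                      merge_duplicates = config$merge_duplicates)
  summary <- as.data.frame(table(chrom = factor(sites$chrom,
                                                levels = names(genome$seqs))),
                           responseName = "n_sites")
  message("scan: ", nrow(sites), " sites on ", length(genome$seqs),
          " chromosome(s)")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sites_bed(sites, file.path(out_dir, "sites.bed"))
    utils::write.table(summary, file.path(out_dir, "site_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(vocab = vocab, sites = sites, summary = summary)
}

#' Run the full cluster-enrichment pipeline
#'
#' Orchestrates scan, background modeling (raw pool plus
#' composition-corrected ensemble), window enumeration, clustering
#' coefficient, the filter cascade, merging, optional annotation and
#' orthology filtering, and ranking. Stage counts are logged and
#' reconcile exactly: every enumerated window is either reported,
#' absorbed into a reported cluster, or flagged with its failure reasons
#' in the verbose window table.
#'
#' @param genome a `genome_assembly`.
#' @param pwm an `ci_pwm`.
#' @param config configuration list ([pipeline_defaults()]); `config$seed`
#'   drives all randomness.
#' @param exons,repeats,ctcf,lifted optional interval data frames; when
#'   `repeats` is `NULL` and the genome is flagged soft-masked, repeat
#'   intervals are derived from lowercase runs.
#' @param models optional gene models ([read_refflat()]) for annotation.
#' @param out_dir optional output directory (`sites.bed`, `windows.tsv`,
#'   `clusters.tsv`, `clusters.bed`, `manifest.yaml`).
#' @return list with `vocab`, `sites`, `pool`, `ensemble`, `windows`
#'   (verbose, flagged), `clusters` (ranked report), `report`
#'   (display tables), `counts` (per-stage bookkeeping).
#' @export
run_pipeline <- function(genome, pwm, config = pipeline_defaults(),
                         exons = NULL, repeats = NULL, ctcf = NULL,
                         lifted = NULL, models = NULL, out_dir = NULL) {
  validate_config(config)
  scan <- run_scan(genome, pwm, config, out_dir = out_dir)
  sites <- scan$sites
  if (!nrow(sites)) stop("pipeline: no binding sites found in the genome")

  if (is.null(repeats) && isTRUE(genome$softmask_as_repeat)) {
    repeats <- softmask_intervals(genome)
    message("pipeline: ", nrow(repeats),
            " repeat interval(s) derived from soft-masking")
  }

  message("background: ", config$n_raw, " raw '", config$model,
          "' genomes -> pooled site positions")
  pool <- build_site_pool(genome, scan$vocab, model = config$model,
                          n_raw = config$n_raw, seed = config$seed)
  ensemble <- reconstruct_backgrounds(
    pool, sites, n_replicates = config$n_replicates,
    seed = if (is.null(config$seed)) NULL else config$seed + 1L)
  message("background: ", config$n_replicates,
          " composition-corrected replicates")

  cc_cfg <- cluster_config(config$min_sites, config$max_sites,
                           config$max_span, config$cc_min,
                           config$anchor_mss, config$site_fraction_max)
  windows <- enumerate_windows(sites, cc_cfg)
  message("clusters: ", nrow(windows), " candidate windows")
  windows$expected <- expected_site_count(windows, ensemble)
  windows$cc <- cluster_coefficient(windows$n_sites, windows$expected,
                                    expected_floor = cc_cfg$expected_floor
                                      %||% (1 / ensemble$n_replicates))
  windows <- apply_filters(windows, sites, exons = exons, repeats = repeats,
                           config = cc_cfg)
  message("clusters: ", sum(windows$pass), "/", nrow(windows),
          " windows pass the filter cascade (cc ", sum(windows$cc_pass),
          ", anchor ", sum(windows$anchor_pass), ", exon ",
          sum(windows$exon_clear), ", repeat ", sum(windows$repeat_clear),
          ", fraction ", sum(windows$fraction_pass), ")")
  clusters <- merge_and_report(windows)
  message("clusters: ", nrow(clusters), " reported after merging")

  if (!is.null(lifted)) {
    before <- nrow(clusters)
    clusters <- ortholog_overlap_filter(clusters, lifted)
    message("orthology: ", nrow(clusters), "/", before,
            " clusters retained (>= 1 bp lifted overlap)")
  } else {
    message("orthology: stage skipped (no lifted intervals supplied)")
  }

  if (!is.null(models)) {
    clusters <- annotate_sites(clusters, models, ctcf = ctcf)
    message("annotation: nearest gene/feature attached")
  }

  clusters <- rank_clusters(clusters)
  report <- cluster_report(clusters, sites)
  counts <- data.frame(
    stage = c("sites", "windows", "windows_pass", "clusters_reported",
              "clusters_final"),
    n = c(nrow(sites), nrow(windows), sum(windows$pass),
          length(unique(c(clusters$cluster_id))), nrow(clusters))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- function(df) df[vapply(df, is.atomic, logical(1L))]
    utils::write.table(flat(windows), file.path(out_dir, "windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(flat(report$clusters),
                       file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(clusters))
      write_bed(data.frame(chrom = clusters$chrom, start = clusters$start,
                           end = clusters$end,
                           name = sprintf("cluster_%d", clusters$rank),
                           score = pmin(1000L, as.integer(
                             round(100 * clusters$cc)))),
                file.path(out_dir, "clusters.bed"))
    manifest <- list(config = config[!vapply(config, is.null, logical(1L))],
                     counts = stats::setNames(as.list(counts$n),
                                              counts$stage))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }

  list(vocab = scan$vocab, sites = sites, pool = pool, ensemble = ensemble,
       windows = windows, clusters = clusters, report = report,
       counts = counts)
}
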