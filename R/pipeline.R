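#' Build a run configuration
#'
#' Exactly one of a simulation block or a set of input paths must be
#' active. Simulation runs generate everything (fragments, NET-seq reads,
#' nucleosome fragments before/after depletion, annotation) from a
#' [sim_params()] object; path runs read user data instead.
#'
#' @param simulation a [sim_params()] object, or `NULL`.
#' @param paths named list of input paths (`fragments`, `peaks`, `tss`,
#'   `orf`, `telomeres`, `netseq`, `nucleosomes_before`,
#'   `nucleosomes_after`), or `NULL`.
#' @param out_dir output directory (created if missing); `NULL` for no
#'   file output.
#' @param seed integer seed for every stochastic stage.
#' @param short_max_length exclusive short-fragment cutoff (default 80).
#' @param bottom_fraction read-depth filter fraction (default 0.15).
#' @param K number of K-means clusters (default 4).
#' @param vplot_halfwidth V-plot window half-width (default 500).
#' @param depletion_shift_bp simulated remodeler-depletion shift
#'   (default 25).
#' @return a `chromfrag_config` list.
#' @export
run_config <- function(simulation = NULL, paths = NULL, out_dir = NULL,
                       seed = 1L, short_max_length = 80L,
                       bottom_fraction = 0.15, K = 4L,
                       vplot_halfwidth = 500L, depletion_shift_bp = 25L) {
  if (!is.null(simulation) && !is.null(paths)) {
    abort("config invalid: supply either `simulation` or `paths`, not both")
  }
  if (is.null(simulation) && is.null(paths)) {
    abort("config invalid: one of `simulation` or `paths` is required")
  }
  if (!is.null(simulation)) {
    stop_if_not(inherits(simulation, "chromfrag_sim_params"),
                "`simulation` must come from sim_params()")
  }
  structure(list(simulation = simulation, paths = paths, out_dir = out_dir,
                 seed = as.integer(seed),
                 short_max_length = as.integer(short_max_length),
                 bottom_fraction = bottom_fraction, K = as.integer(K),
                 vplot_halfwidth = as.integer(vplot_halfwidth),
                 depletion_shift_bp = as.integer(depletion_shift_bp)),
            class = "chromfrag_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis: footprint, V-plot, clustering, NET-seq split,
#' nucleosome shifts
#'
#' Sequences simulation (or ingest), the pre-clustering filters, fragment
#' end stacking and footprint estimation, the V-plot, per-site
#' fragment-length profiles and K-means classification, long-fragment
#' asymmetry per cluster, aborted-transcript scoring with the cluster-K
#' subcluster split, and nucleosome-shift quantification per
#' cluster/subcluster. Every stage logs its input/output counts; TSV
#' outputs and a machine-readable JSON summary are written when
#' `out_dir` is set.
#'
#' @param cfg a [run_config()] object.
#' @return a `chromfrag_report` list: `summary` (plain list, also written
#'   as JSON), `clusters`, `asymmetry`, `subclusters`, `shifts`,
#'   `filter_report`, `vmatrix`, `end_profiles`.
#' @export
run_analysis <- function(cfg) {
  stop_if_not(inherits(cfg, "chromfrag_config"),
              "`cfg` must come from run_config()")
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }

  if (!is.null(cfg$simulation)) {
    p <- cfg$simulation
    panel <- build_site_panel(p)
    frags <- simulate_chip_fragments(panel, p)
    reads <- simulate_netseq_reads(panel, reads_per_site = 200L,
                                   seed = p$seed + 2L)
    nuc_before <- simulate_nucleosome_fragments(panel, depleted = FALSE,
                                                shift_bp = cfg$depletion_shift_bp,
                                                seed = p$seed + 3L,
                                                fragments_per_site = 400L)
    nuc_after <- simulate_nucleosome_fragments(panel, depleted = TRUE,
                                               shift_bp = cfg$depletion_shift_bp,
                                               seed = p$seed + 3L,
                                               fragments_per_site = 400L)
    ann <- panel_annotation(panel)
    anchors <- panel_anchors(panel, "tss")
    motif_anchors <- panel_anchors(panel, "motif")
    # peak bookkeeping over the simulated sites, read depth from coverage
    peaks <- tibble(chrom = anchors$chrom, start = anchors$position - 100L,
                    end = anchors$position + 100L, name = anchors$anchor_id,
                    score = 0, summit = anchors$position,
                    has_motif = TRUE)
    peaks <- peak_read_coverage(peaks, frags)
    peaks$read_count <- peaks$norm_coverage
    log_stage("simulate", "%d sites, %d fragments, %d NET-seq reads",
              nrow(panel$sites), nrow(frags), nrow(reads))
    telomeres <- panel$telomeres
  } else {
    pth <- cfg$paths
    frags <- read_fragments(pth$fragments)
    peaks <- read_peaks(pth$peaks)
    ann <- read_annotation(pth$tss, pth$orf, pth$telomeres)
    telomeres <- ann$telomeres
    reads <- if (!is.null(pth$netseq)) read_stranded_reads(pth$netseq) else NULL
    nuc_before <- if (!is.null(pth$nucleosomes_before))
      read_fragments(pth$nucleosomes_before) else NULL
    nuc_after <- if (!is.null(pth$nucleosomes_after))
      read_fragments(pth$nucleosomes_after) else NULL
    if (!"has_motif" %in% names(peaks)) peaks$has_motif <- TRUE
    if (!"read_count" %in% names(peaks) || all(peaks$read_count == 0)) {
      peaks <- peak_read_coverage(peaks, frags)
      peaks$read_count <- peaks$norm_coverage
    }
    tssa <- assign_nearest_tss(peaks, ann)
    anchors <- tssa
    motif_anchors <- tssa
    log_stage("ingest", "%d fragments, %d peaks", nrow(frags), nrow(peaks))
  }

  filt <- apply_clustering_filters(peaks, cfg$bottom_fraction)
  log_stage("filters", "input %d -> no-motif -%d, low-count -%d -> %d",
            filt$report$n[1], filt$report$n[2], filt$report$n[3],
            filt$report$n[4])
  kept_ids <- if ("name" %in% names(filt$peaks)) filt$peaks$name else
    filt$peaks$anchor_id
  anchors_kept <- anchors[anchors$anchor_id %in% kept_ids, ]

  short <- select_by_length(frags, 1L, cfg$short_max_length)
  ep <- end_profiles(short, motif_anchors, W = 40L)
  fw <- tryCatch(estimate_footprint_width(ep, flank = 40L),
                 error = function(e) list(width = NA_integer_, left = NA,
                                          right = NA))
  log_stage("footprint", "width %s bp (boundaries %s..%s)",
            fw$width, fw$left, fw$right)

  vm <- vplot(frags, anchors_kept, W = cfg$vplot_halfwidth)
  profs <- length_profiles(anchors_kept, frags)
  cl <- cluster_profiles(profs, K = cfg$K, seed = cfg$seed)
  log_stage("cluster", "K = %d, sizes %s", cl$K,
            paste(cl$sizes, collapse = "/"))

  asym <- long_fragment_asymmetry(frags, anchors_kept)
  asym <- dplyr::left_join(asym, cl$assignments,
                           by = c(anchor_id = "peak_id"))
  asym_by_cluster <- asym |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(mean_score = mean(.data$score, na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop")

  subclusters <- NULL
  shifts <- list()
  if (!is.null(reads)) {
    c4_ids <- cl$assignments$peak_id[cl$assignments$cluster == cl$K]
    c4_anchors <- anchors_kept[anchors_kept$anchor_id %in% c4_ids, ]
    scores <- aborted_transcript_score(reads, c4_anchors)
    if (nrow(scores) >= 2 && length(unique(scores$score)) > 1) {
      subclusters <- split_cluster4(scores)
      log_stage("netseq", "cluster %d split: %d locked (4a) / %d pushed (4b)",
                cl$K, sum(subclusters$sublabel == "4a"),
                sum(subclusters$sublabel == "4b"))
    }
  }
  if (!is.null(nuc_before) && !is.null(nuc_after)) {
    groups <- list(cluster1 = cl$assignments$peak_id[cl$assignments$cluster == 1])
    if (!is.null(subclusters)) {
      groups$cluster4a <- subclusters$anchor_id[subclusters$sublabel == "4a"]
      groups$cluster4b <- subclusters$anchor_id[subclusters$sublabel == "4b"]
    }
    shifts <- purrr::imap(groups, function(ids, nm) {
      ga <- anchors_kept[anchors_kept$anchor_id %in% ids, ]
      if (nrow(ga) == 0) return(NULL)
      pb <- nucleosome_profile(nuc_before, ga, telomeres = telomeres)
      pa <- nucleosome_profile(nuc_after, ga, telomeres = telomeres)
      nucleosome_shift(pb, pa)
    })
    shifts <- shifts[!vapply(shifts, is.null, logical(1))]
    for (nm in names(shifts)) {
      s <- shifts[[nm]]
      log_stage("shift", "%s: -1 %+d bp, +1 %+d bp", nm,
                s$shift[s$side == "minus1"], s$shift[s$side == "plus1"])
    }
  }

  summary <- list(
    n_fragments = nrow(frags),
    filter_counts = stats::setNames(as.list(filt$report$n),
                                    filt$report$stage),
    footprint_width = fw$width,
    footprint_boundaries = c(fw$left, fw$right),
    cluster_sizes = as.list(stats::setNames(cl$sizes,
                                            paste0("cluster", seq_len(cl$K)))),
    asymmetry_by_cluster = stats::setNames(
      as.list(round(asym_by_cluster$mean_score, 4)),
      paste0("cluster", asym_by_cluster$cluster)),
    subcluster_sizes = if (!is.null(subclusters)) {
      as.list(table(subclusters$sublabel))
    } else NULL,
    shifts = purrr::map(shifts, function(s) {
      stats::setNames(as.list(s$shift), s$side)
    }),
    seed = cfg$seed)

  if (!is.null(cfg$out_dir)) {
    readr::write_tsv(filt$report, file.path(cfg$out_dir, "filter_report.tsv"))
    readr::write_tsv(tidy(cl), file.path(cfg$out_dir, "clusters.tsv"))
    readr::write_tsv(asym, file.path(cfg$out_dir, "asymmetry.tsv"))
    readr::write_tsv(tidy(vm), file.path(cfg$out_dir, "vmatrix.tsv"))
    readr::write_tsv(as_tibble(ep), file.path(cfg$out_dir, "end_profiles.tsv"))
    if (!is.null(subclusters)) {
      readr::write_tsv(subclusters, file.path(cfg$out_dir, "subclusters.tsv"))
    }
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(summary = summary, clusters = cl, asymmetry = asym,
                 subclusters = subclusters, shifts = shifts,
                 filter_report = filt$report, vmatrix = vm,
                 end_profiles = ep),
            class = "chromfrag_report")
}

#' @export
print.chromfrag_report <- function(x, ...) {
  cat("<chromfrag analysis report>\n")
  cat("fragments:", x$summary$n_fragments, "\n")
  cat("footprint width:", x$summary$footprint_width, "bp\n")
  cat("cluster sizes:",
      paste(unlist(x$summary$cluster_sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a miniature simulated dataset for examples and tests
#'
#' A small panel (5 sites per class, 100 fragments per site) written as
#' plain-text files: ChIP fragments and nucleosome fragments before/after
#' remodeler depletion (BED6, ground-truth class in the name field),
#' NET-seq 3' ends (stranded BED6), peak calls (BED6), the site table,
#' and TSS/ORF/telomere annotation (TSV).
#'
#' @param dir output directory.
#' @param seed integer seed; identical seeds give identical fixtures.
#' @return named list of file paths, invisibly; the panel as attribute
#'   `panel`.
#' @export
make_fixture <- function(dir = tempfile("chromfrag_fixture"), seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- sim_params(n_sites_per_class = 5L, fragments_per_site = 100L,
                  seed = as.integer(seed))
  panel <- build_site_panel(p)
  frags <- simulate_chip_fragments(panel, p)
  reads <- simulate_netseq_reads(panel, reads_per_site = 100L,
                                 seed = p$seed + 2L)
  nuc_before <- simulate_nucleosome_fragments(panel, depleted = FALSE,
                                              fragments_per_site = 100L,
                                              seed = p$seed + 3L)
  nuc_after <- simulate_nucleosome_fragments(panel, depleted = TRUE,
                                             fragments_per_site = 100L,
                                             seed = p$seed + 3L)
  ann <- panel_annotation(panel)
  peaks <- tibble(chrom = panel$sites$chrom,
                  start = panel$sites$motif_center - 100L,
                  end = panel$sites$motif_center + 100L,
                  name = panel$sites$site_id, score = 0, strand = ".")
  paths <- list(
    fragments = file.path(dir, "fragments.bed"),
    peaks = file.path(dir, "peaks.bed"),
    netseq = file.path(dir, "netseq.bed"),
    nucleosomes_before = file.path(dir, "nucleosomes_before.bed"),
    nucleosomes_after = file.path(dir, "nucleosomes_after.bed"),
    sites = file.path(dir, "sites.tsv"),
    tss = file.path(dir, "tss.tsv"),
    orf = file.path(dir, "orf.tsv"),
    telomeres = file.path(dir, "telomeres.tsv"))
  write_bed(frags, paths$fragments)
  write_bed(peaks, paths$peaks)
  write_stranded_reads(reads, paths$netseq)
  write_bed(nuc_before, paths$nucleosomes_before)
  write_bed(nuc_after, paths$nucleosomes_after)
  readr::write_tsv(panel$sites, paths$sites)
  readr::write_tsv(ann$tss, paths$tss)
  readr::write_tsv(ann$orf, paths$orf)
  readr::write_tsv(ann$telomeres, paths$telomeres)
  attr(paths, "panel") <- panel
  invisible(paths)
}
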