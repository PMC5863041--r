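#' Read peaks from BED or narrowPeak
#'
#' narrowPeak column 10 is the summit offset from `start` (-1 for
#' missing); the summit falls back to the interval midpoint (floor).
#'
#' @param path peak file.
#' @param format `"bed"` or `"narrowpeak"` (guessed from the extension).
#' @return peak tibble: chrom, start, end, name, score, summit,
#'   read_count.
#' @export
read_peaks <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("narrow[pP]eak$", path)) "narrowpeak" else "bed"
  }
  format <- match.arg(format, c("bed", "narrowpeak"))
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & lines != ""]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), summit = integer(),
                  read_count = numeric()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  col <- function(k, default = NA_character_) {
    vapply(f, function(x) if (length(x) >= k) x[k] else default, "")
  }
  start <- as.integer(col(2))
  end <- as.integer(col(3))
  summit_off <- if (format == "narrowpeak") {
    suppressWarnings(as.integer(col(10, "-1")))
  } else {
    rep(-1L, length(start))
  }
  summit <- ifelse(!is.na(summit_off) & summit_off >= 0,
                   start + summit_off, peak_center(start, end))
  tibble(chrom = col(1), start = start, end = end,
         name = col(4, "."),
         score = suppressWarnings(as.numeric(col(5, "0"))),
         summit = as.integer(summit),
         read_count = suppressWarnings(as.numeric(col(7, "0"))))
}

# Peak "center": the summit when available, else interval midpoint (floor).
peak_center <- function(start, end) {
  as.integer(floor((start + end - 1) / 2))
}

check_peaks <- function(ps) {
  stop_if_not(is.data.frame(ps) && "chrom" %in% names(ps),
              "peaks must be a data frame with a chrom column")
  ps <- as_tibble(ps)
  if (!"summit" %in% names(ps)) {
    stop_if_not(all(c("start", "end") %in% names(ps)),
                "peaks need either a summit or start/end columns")
    ps$summit <- peak_center(ps$start, ps$end)
  }
  ps
}

#' Match peak sets by center distance and count Venn cells
#'
#' Two peaks from different sets match when they lie on the same
#' chromosome and the distance between their centers is strictly below
#' `max_dist`. For more than two sets, the pairwise match edges form a
#' graph whose connected components are the matched groups; each group is
#' labelled by the set-membership signature (the sorted set names it
#' touches), and the Venn cell counts are counts of components per
#' signature.
#'
#' @param sets named list of 2-3 peak tibbles.
#' @param max_dist exclusive center-distance threshold in bp (default 64).
#' @return list with `groups` (tibble: set, peak row, group id, signature)
#'   and `venn` (tibble: signature, n_groups).
#' @export
match_peak_sets <- function(sets, max_dist = 64L) {
  stop_if_not(is.list(sets) && length(sets) >= 2,
              "`sets` must be a named list of at least 2 peak sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, check_peaks)
  nodes <- purrr::imap(sets, function(ps, nm) {
    tibble(set = nm, peak = seq_len(nrow(ps)), chrom = ps$chrom,
           center = ps$summit)
  }) |> dplyr::bind_rows()
  nodes$node <- seq_len(nrow(nodes))
  edges <- list()
  combs <- utils::combn(names(sets), 2, simplify = FALSE)
  for (pr in combs) {
    a <- nodes[nodes$set == pr[1], ]
    b <- nodes[nodes$set == pr[2], ]
    if (nrow(a) == 0 || nrow(b) == 0) next
    hit <- dplyr::inner_join(a, b, by = "chrom", suffix = c(".a", ".b"),
                             relationship = "many-to-many")
    hit <- hit[abs(hit$center.a - hit$center.b) < max_dist, ]
    edges[[length(edges) + 1L]] <- hit[, c("node.a", "node.b")]
  }
  edges <- dplyr::bind_rows(edges)
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$node.a, edges$node.b))
  }
  comp <- igraph::components(g)$membership
  nodes$group <- comp
  sig <- vapply(split(nodes$set, nodes$group),
                function(s) paste(sort(unique(s)), collapse = "+"), "")
  nodes$signature <- unname(sig[as.character(nodes$group)])
  venn <- tibble(signature = unname(sig)) |>
    dplyr::count(.data$signature, name = "n_groups")
  list(groups = as_tibble(nodes[, c("set", "peak", "chrom", "center",
                                    "group", "signature")]),
       venn = venn)
}

#' Normalized read coverage per peak
#'
#' For each peak, sums per-base fragment coverage over the window
#' `[summit - halfwidth, summit + halfwidth]` (inclusive; 151 bases at
#' the default 75) and scales by `1e6 / total fragments` in the library.
#'
#' @param ps peak tibble with summits.
#' @param fs fragment tibble (the whole library; its size sets the
#'   normalization).
#' @param halfwidth window half-width in bp (default 75).
#' @return `ps` with an added `norm_coverage` column.
#' @export
peak_read_coverage <- function(ps, fs, halfwidth = 75L) {
  ps <- check_peaks(ps)
  fs <- check_fragments(fs)
  if (nrow(fs) == 0) {
    warn("empty fragment set: all coverages are zero")
    ps$norm_coverage <- 0
    return(ps)
  }
  cov <- coverage_rle(fs)
  scale <- 1e6 / nrow(fs)
  ps$norm_coverage <- purrr::map_dbl(seq_len(nrow(ps)), function(i) {
    rle <- cov[[ps$chrom[i]]]
    sum(rle_window(rle, ps$summit[i] - halfwidth,
                   ps$summit[i] + halfwidth)) * scale
  })
  ps
}

#' Sample random background locations
#'
#' Uniform positions over the genome (chromosomes weighted by length),
#' returned as summit-only peaks; deterministic given the seed.
#'
#' @param chrom_sizes tibble chrom, size.
#' @param n number of locations (default 500).
#' @param seed integer seed.
#' @return peak tibble with summits.
#' @export
sample_background <- function(chrom_sizes, n = 500L, seed = 1L) {
  stop_if_not(n >= 1, "`n` must be >= 1")
  withr::with_seed(as.integer(seed), {
    chrom <- sample(chrom_sizes$chrom, n, replace = TRUE,
                    prob = chrom_sizes$size)
    size <- chrom_sizes$size[match(chrom, chrom_sizes$chrom)]
    summit <- as.integer(floor(stats::runif(n) * size))
  })
  tibble(chrom = chrom, start = pmax(summit - 1L, 0L), end = summit + 1L,
         name = paste0("bg_", seq_len(n)), score = 0, summit = summit,
         read_count = 0)
}

#' Fraction of peaks whose center lies within an ORF
#'
#' A peak is inside an ORF when its summit satisfies
#' `start <= summit < end` for some ORF interval (half-open).
#'
#' @param ps peak tibble.
#' @param annotation annotation list with an `orf` tibble.
#' @return list with `peaks` (`ps` plus logical `in_orf`) and
#'   `percent_in_orf`.
#' @export
classify_orf_location <- function(ps, annotation) {
  ps <- check_peaks(ps)
  orf <- annotation$orf
  if (nrow(ps) == 0) {
    return(list(peaks = ps, percent_in_orf = NA_real_))
  }
  ps$in_orf <- purrr::map_lgl(seq_len(nrow(ps)), function(i) {
    o <- orf[orf$chrom == ps$chrom[i], ]
    any(o$start <= ps$summit[i] & ps$summit[i] < o$end)
  })
  list(peaks = ps, percent_in_orf = 100 * mean(ps$in_orf))
}

#' Assign the nearest TSS to each peak and orient it by gene direction
#'
#' Peaks farther than `max_dist` bp from the nearest TSS are discarded
#' (strictly: distance > `max_dist` discards, so distance = `max_dist`
#' is retained). Equidistant TSS ties go to the lower coordinate.
#'
#' @param ps peak tibble.
#' @param annotation annotation list with a `tss` tibble.
#' @param max_dist inclusive distance cutoff in bp (default 256).
#' @return anchor tibble (chrom, position = summit, orientation = gene
#'   strand, anchor_id, gene_id, tss_pos, tss_distance) with attribute
#'   `n_discarded`.
#' @export
assign_nearest_tss <- function(ps, annotation, max_dist = 256L) {
  ps <- check_peaks(ps)
  tss <- annotation$tss
  stop_if_not(nrow(tss) > 0, "TSS table is empty")
  rows <- purrr::map(seq_len(nrow(ps)), function(i) {
    t <- tss[tss$chrom == ps$chrom[i], ]
    if (nrow(t) == 0) return(NULL)
    d <- abs(t$pos - ps$summit[i])
    j <- which(d == min(d))
    if (length(j) > 1) j <- j[which.min(t$pos[j])]  # tie: lower coordinate
    tibble(chrom = ps$chrom[i], position = ps$summit[i],
           orientation = t$strand[j],
           anchor_id = if ("name" %in% names(ps)) ps$name[i] else
             paste0("peak_", i),
           gene_id = if ("gene_id" %in% names(t)) t$gene_id[j] else
             NA_character_,
           tss_pos = t$pos[j], tss_distance = d[j])
  })
  out <- dplyr::bind_rows(rows)
  keep <- out$tss_distance <= max_dist
  res <- out[keep, ]
  attr(res, "n_discarded") <- sum(!keep) + (nrow(ps) - nrow(out))
  res
}

#' Pre-clustering peak filters: motif presence, then read depth
#'
#' First discards peaks without a motif (`has_motif` false or `motif`
#' missing), then the `ceiling(bottom_fraction * n_remaining)` peaks with
#' the smallest read counts (ties broken by input order).
#'
#' @param ps peak tibble with a `read_count` column and either a logical
#'   `has_motif` column or a `motif` list-column with `NULL`/`NA` for
#'   motif-less peaks.
#' @param bottom_fraction fraction of motif-bearing peaks to drop by read
#'   count (default 0.15).
#' @return list with `peaks` (retained) and `report` (tibble of stage
#'   counts: input, no_motif, low_count, retained).
#' @export
apply_clustering_filters <- function(ps, bottom_fraction = 0.15) {
  ps <- check_peaks(ps)
  stop_if_not(bottom_fraction >= 0 && bottom_fraction < 1,
              "`bottom_fraction` must be in [0, 1)")
  n_in <- nrow(ps)
  has_motif <- if ("has_motif" %in% names(ps)) {
    as.logical(ps$has_motif)
  } else if ("motif" %in% names(ps)) {
    !vapply(ps$motif, function(m) is.null(m) || all(is.na(m)), logical(1))
  } else {
    rep(TRUE, n_in)
  }
  ps1 <- ps[has_motif, ]
  n_no_motif <- n_in - nrow(ps1)
  n_drop <- as.integer(ceiling(bottom_fraction * nrow(ps1)))
  if (n_drop > 0 && nrow(ps1) > 0) {
    ord <- order(ps1$read_count, seq_len(nrow(ps1)))
    drop_idx <- ord[seq_len(n_drop)]
    ps2 <- ps1[-drop_idx, ]
  } else {
    ps2 <- ps1
  }
  list(peaks = ps2,
       report = tibble(stage = c("input", "no_motif", "low_count", "retained"),
                       n = c(n_in, n_no_motif, n_drop, nrow(ps2))))
}
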