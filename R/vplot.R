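#' V-plot: 2-D histogram of fragment midpoint offset by fragment length
#'
#' Each fragment maps to `(offset, length)` where offset is the oriented
#' distance from the fragment midpoint (floor of the mean of the two
#' inclusive end coordinates) to the anchor. Fragments with `|offset| > W`
#' or length outside `[Lmin, Lmax]` are dropped and counted.
#'
#' @param fs fragment tibble.
#' @param anchors anchor tibble.
#' @param W offset half-width in bp (default 500).
#' @param Lmin,Lmax inclusive length range (defaults 40/250).
#' @return a `chromfrag_vmatrix`: integer matrix (rows = lengths
#'   Lmin..Lmax, columns = offsets -W..W) with attributes `n_used` and
#'   `n_dropped`.
#' @export
vplot <- function(fs, anchors, W = 500L, Lmin = 40L, Lmax = 250L) {
  stop_if_not(Lmin < Lmax, "`Lmin` must be smaller than `Lmax`")
  fs <- check_fragments(fs)
  anchors <- check_anchors(anchors)
  lens <- Lmin:Lmax
  offs <- (-W):W
  m <- matrix(0L, nrow = length(lens), ncol = length(offs),
              dimnames = list(length = lens, offset = offs))
  n_used <- 0L
  n_dropped <- 0L
  mid_all <- fragment_midpoint(fs$start, fs$end)
  len_all <- fs$end - fs$start
  for (i in seq_len(nrow(anchors))) {
    k <- fs$chrom == anchors$chrom[i]
    if (!any(k)) next
    off <- oriented_offset(mid_all[k], anchors$position[i],
                           anchors$orientation[i])
    len <- len_all[k]
    near <- abs(off) <= W + Lmax  # fragments plausibly tied to this anchor
    inr <- abs(off) <= W & len >= Lmin & len <= Lmax
    n_used <- n_used + sum(inr)
    n_dropped <- n_dropped + sum(near & !inr)
    if (any(inr)) {
      idx <- cbind(len[inr] - Lmin + 1L, off[inr] + W + 1L)
      counts <- table(paste(idx[, 1], idx[, 2]))
      parts <- do.call(rbind, strsplit(names(counts), " "))
      m[cbind(as.integer(parts[, 1]), as.integer(parts[, 2]))] <-
        m[cbind(as.integer(parts[, 1]), as.integer(parts[, 2]))] +
        as.integer(counts)
    }
  }
  structure(m, n_used = n_used, n_dropped = n_dropped,
            class = c("chromfrag_vmatrix", class(m)))
}

#' @export
print.chromfrag_vmatrix <- function(x, ...) {
  cat(sprintf("<V-matrix: %d lengths x %d offsets, %d fragments>\n",
              nrow(x), ncol(x), attr(x, "n_used")))
  invisible(x)
}

#' Tidy a V-matrix into a long tibble
#' @param x a `chromfrag_vmatrix`.
#' @param ... unused.
#' @return tibble offset, length, count.
#' @method tidy chromfrag_vmatrix
#' @export
tidy.chromfrag_vmatrix <- function(x, ...) {
  tibble(offset = rep(as.integer(colnames(x)), each = nrow(x)),
         length = rep(as.integer(rownames(x)), times = ncol(x)),
         count = as.integer(x))
}

# 21 left-closed 10-bp bins on [40, 250]; the top bin is right-closed so
# a 250-bp fragment lands in [240, 250].
length_bin_edges <- seq(40L, 250L, by = 10L)

length_bin_labels <- function() {
  lo <- length_bin_edges[-length(length_bin_edges)]
  sprintf("len_%d_%d", lo, lo + 10L)
}

assign_length_bin <- function(len) {
  bin <- ifelse(len >= 40L & len <= 250L,
                pmin(floor((len - 40L) / 10L) + 1L, 21L), NA_integer_)
  as.integer(bin)
}

#' Fragment-length profiles per peak
#'
#' Each peak is summarized by the fraction of its fragments in 21 10-bp
#' length bins spanning 40-250 bp. A fragment is assigned to a peak when
#' its midpoint lies within `summit +/- halfwidth`; fragments outside the
#' length range are ignored. Peaks with no in-range fragments are flagged
#' empty (`n_fragments = 0`, all fractions `NA`) and excluded from
#' clustering.
#'
#' @param ps peak tibble with summits (or an anchor tibble; `position`
#'   is used as the summit).
#' @param fs fragment tibble.
#' @param halfwidth peak-region half-width in bp (default 100).
#' @return tibble: peak_id, n_fragments, and 21 `len_*` fraction columns.
#' @export
length_profiles <- function(ps, fs, halfwidth = 100L) {
  fs <- check_fragments(fs)
  ps <- as_tibble(ps)
  if ("position" %in% names(ps) && !"summit" %in% names(ps)) {
    ps$summit <- ps$position
  }
  ps <- check_peaks(ps)
  id <- if ("anchor_id" %in% names(ps)) ps$anchor_id else
    if ("name" %in% names(ps) && !anyDuplicated(ps$name)) ps$name else
      paste0("peak_", seq_len(nrow(ps)))
  mid <- fragment_midpoint(fs$start, fs$end)
  len <- fs$end - fs$start
  bins <- assign_length_bin(len)
  labs <- length_bin_labels()
  rows <- purrr::map(seq_len(nrow(ps)), function(i) {
    k <- fs$chrom == ps$chrom[i] &
      mid >= ps$summit[i] - halfwidth & mid <= ps$summit[i] + halfwidth &
      !is.na(bins)
    n <- sum(k)
    frac <- if (n > 0) tabulate(bins[k], nbins = 21L) / n else
      rep(NA_real_, 21L)
    out <- tibble(peak_id = id[i], n_fragments = n)
    out[labs] <- as.list(frac)
    out
  })
  dplyr::bind_rows(rows)
}

# Fraction of a profile's mass in the long bins (length >= 160 bp,
# bins 13..21) -- the canonical cluster-ordering key.
long_fraction <- function(mat) {
  rowSums(mat[, 13:21, drop = FALSE])
}

#' K-means classification of fragment-length profiles
#'
#' Clusters the 21-bin fraction vectors with K-means (Euclidean distance,
#' best of `restarts` seeded initializations by total within-cluster sum
#' of squares). Clusters are relabeled canonically by ascending centroid
#' long-fraction (mass in bins >= 160 bp), so cluster 1 is the most
#' short-fragment-dominated and cluster K the most co-bound-dominated.
#'
#' @param profiles a [length_profiles()] tibble; empty profiles are
#'   dropped with a message.
#' @param K number of clusters (default 4).
#' @param seed integer seed.
#' @param restarts K-means restarts (default 25).
#' @return a `chromfrag_kmeans`: list with `assignments` (tibble peak_id,
#'   cluster), `centroids` (K x 21 matrix, canonical order), `sizes`,
#'   `tot_withinss`, `K`, `seed`, `restarts`.
#' @export
cluster_profiles <- function(profiles, K = 4L, seed = 1L, restarts = 25L) {
  labs <- length_bin_labels()
  stop_if_not(all(labs %in% names(profiles)),
              "`profiles` must come from length_profiles()")
  keep <- profiles$n_fragments > 0
  if (any(!keep)) {
    message(sprintf("dropping %d empty profile(s)", sum(!keep)))
  }
  profiles <- profiles[keep, ]
  stop_if_not(nrow(profiles) >= K,
              "need at least K non-empty profiles to cluster")
  mat <- as.matrix(profiles[, labs])
  km <- withr::with_seed(as.integer(seed),
                         stats::kmeans(mat, centers = K, nstart = restarts,
                                       iter.max = 100L))
  ord <- order(long_fraction(km$centers))
  relabel <- integer(K)
  relabel[ord] <- seq_len(K)
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(K)
  structure(
    list(assignments = tibble(peak_id = profiles$peak_id,
                              cluster = relabel[km$cluster]),
         centroids = centroids,
         sizes = as.integer(table(factor(relabel[km$cluster],
                                         levels = seq_len(K)))),
         tot_withinss = km$tot.withinss,
         K = as.integer(K), seed = as.integer(seed),
         restarts = as.integer(restarts)),
    class = "chromfrag_kmeans")
}

#' @export
print.chromfrag_kmeans <- function(x, ...) {
  cat(sprintf("<fragment-length K-means: K = %d, n = %d>\n",
              x$K, nrow(x$assignments)))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("centroid long-fraction (>=160 bp):",
      paste(sprintf("%.3f", long_fraction(x$centroids)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @method tidy chromfrag_kmeans
#' @export
tidy.chromfrag_kmeans <- function(x, ...) {
  x$assignments
}

#' @method glance chromfrag_kmeans
#' @export
glance.chromfrag_kmeans <- function(x, ...) {
  tibble(K = x$K, n = nrow(x$assignments),
         tot_withinss = x$tot_withinss,
         max_long_fraction = max(long_fraction(x$centroids)))
}

#' TSS-relative asymmetry of long (co-bound-sized) fragments
#'
#' Among fragments in the long length range that cover the anchor
#' position, the score is `(upstream - downstream) / total` of midpoint
#' placements, where upstream means the TSS-distal side (negative
#' oriented offsets; anchors must be oriented so positive offsets point
#' toward the TSS). A site whose long fragments all sit over the -1
#' nucleosome scores 1; balanced placement scores 0.
#'
#' @param fs fragment tibble.
#' @param anchors TSS-oriented anchor tibble.
#' @param long_range inclusive length bounds (default `c(160, 220)`).
#' @return tibble anchor_id, n_long, score (NA when no long fragments).
#' @export
long_fragment_asymmetry <- function(fs, anchors, long_range = c(160L, 220L)) {
  fs <- check_fragments(fs)
  anchors <- check_anchors(anchors)
  len <- fs$end - fs$start
  mid <- fragment_midpoint(fs$start, fs$end)
  long <- len >= long_range[1] & len <= long_range[2]
  rows <- purrr::map(seq_len(nrow(anchors)), function(i) {
    a <- anchors$position[i]
    k <- long & fs$chrom == anchors$chrom[i] &
      fs$start <= a & fs$end - 1L >= a    # must cover the anchor base
    n <- sum(k)
    if (n == 0) {
      return(tibble(anchor_id = anchors$anchor_id[i], n_long = 0L,
                    score = NA_real_))
    }
    off <- oriented_offset(mid[k], a, anchors$orientation[i])
    tibble(anchor_id = anchors$anchor_id[i], n_long = n,
           score = (sum(off < 0) - sum(off >= 0)) / n)
  })
  dplyr::bind_rows(rows)
}
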