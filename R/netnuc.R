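#' Strand-split nascent-transcription coverage around oriented anchors
#'
#' Each 3'-end read is extended `extension` bp in the 5' direction and
#' contributes coverage over `extension + 1` inclusive bases
#' (`[p - extension, p]` on the plus strand, `[p, p + extension]` on the
#' minus strand). Reads are split into sense (read strand equals the
#' anchor orientation) and antisense; coverage is accumulated in oriented
#' offsets and summed over anchors. Anchors lying inside telomere
#' intervals are dropped first.
#'
#' @param reads stranded read tibble (chrom, pos, strand).
#' @param anchors TSS-oriented anchor tibble.
#' @param W window half-width in bp (default 500).
#' @param extension 5' extension in bp (default 20).
#' @param telomeres optional tibble chrom/start/end; anchors inside are
#'   discarded.
#' @return tibble offset, sense, antisense with attribute
#'   `n_anchors_used`.
#' @export
netseq_coverage <- function(reads, anchors, W = 500L, extension = 20L,
                            telomeres = NULL) {
  stop_if_not(extension >= 0, "`extension` must be >= 0")
  stop_if_not(all(reads$strand %in% c("+", "-")),
              "reads must be stranded '+'/'-'")
  anchors <- check_anchors(anchors)
  drop <- in_telomere(anchors, telomeres)
  anchors <- anchors[!drop, ]
  sense <- numeric(2L * W + 1L)
  anti <- numeric(2L * W + 1L)
  lo_g <- ifelse(reads$strand == "+", reads$pos - extension, reads$pos)
  hi_g <- ifelse(reads$strand == "+", reads$pos, reads$pos + extension)
  for (i in seq_len(nrow(anchors))) {
    a <- anchors$position[i]
    k <- reads$chrom == anchors$chrom[i] &
      hi_g >= a - W & lo_g <= a + W
    if (!any(k)) next
    is_sense <- reads$strand[k] == anchors$orientation[i]
    if (anchors$orientation[i] == "+") {
      lo <- lo_g[k] - a; hi <- hi_g[k] - a
    } else {
      lo <- a - hi_g[k]; hi <- a - lo_g[k]
    }
    lo <- pmax(lo, -W); hi <- pmin(hi, W)
    for (j in seq_along(lo)) {
      idx <- (lo[j] + W + 1L):(hi[j] + W + 1L)
      if (is_sense[j]) sense[idx] <- sense[idx] + 1
      else anti[idx] <- anti[idx] + 1
    }
  }
  out <- tibble(offset = (-W):W, sense = sense, antisense = anti)
  attr(out, "n_anchors_used") <- nrow(anchors)
  out
}

#' Aborted-transcript score per anchor
#'
#' Counts antisense 3' ends in the window `[anchor - window_upstream,
#' anchor]` (oriented; the motif-proximal upstream side), normalized per
#' 1000 antisense reads falling within `+/- W` of the anchor — the score
#' depends on antisense reads only, so it is invariant to the
#' sense-transcription level. High scores mark sites with short antisense
#' transcripts terminating at the bound factor.
#'
#' @param reads stranded read tibble.
#' @param anchors TSS-oriented anchor tibble.
#' @param window_upstream upstream window in bp (default 50).
#' @param W in-window normalization half-width (default 500).
#' @return tibble anchor_id, n_antisense, n_aborted, score, flag
#'   (`"no_reads"` when an anchor has no in-window antisense reads;
#'   score 0).
#' @export
aborted_transcript_score <- function(reads, anchors, window_upstream = 50L,
                                     W = 500L) {
  anchors <- check_anchors(anchors)
  rows <- purrr::map(seq_len(nrow(anchors)), function(i) {
    a <- anchors$position[i]
    k <- reads$chrom == anchors$chrom[i] & abs(reads$pos - a) <= W &
      reads$strand != anchors$orientation[i]
    n <- sum(k)
    if (n == 0) {
      return(tibble(anchor_id = anchors$anchor_id[i], n_antisense = 0L,
                    n_aborted = 0L, score = 0, flag = "no_reads"))
    }
    off <- oriented_offset(reads$pos[k], a, anchors$orientation[i])
    n_ab <- sum(off >= -window_upstream & off <= 0)
    tibble(anchor_id = anchors$anchor_id[i], n_antisense = n,
           n_aborted = as.integer(n_ab), score = 1000 * n_ab / n,
           flag = NA_character_)
  })
  dplyr::bind_rows(rows)
}

# Exact 1-D 2-means: enumerate all sorted split points and minimize the
# within-group sum of squares. Deterministic; optimal for K = 2 in 1-D
# because optimal clusters are contiguous in sorted order.
split_1d_2means <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  best <- NULL
  best_ss <- Inf
  for (k in seq_len(n - 1)) {
    a <- xs[1:k]; b <- xs[(k + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best <- k
    }
  }
  grp <- integer(n)
  grp[ord] <- rep(c(1L, 2L), c(best, n - best))  # 2 = higher-score group
  grp
}

#' Split cluster-4 anchors into locked (4a) and pushed (4b) subclusters
#'
#' Exact two-group 1-D K-means on the aborted-transcript scores; the
#' higher-score group is labeled `"4a"` (aborted transcripts present,
#' remodeler-locked -1 nucleosome), the lower `"4b"`. If all scores are
#' identical the split is refused and every anchor gets a single flagged
#' group.
#'
#' @param scores an [aborted_transcript_score()] tibble (or a numeric
#'   vector with names).
#' @return tibble anchor_id, score, sublabel (`"4a"`/`"4b"`, or `"4"`
#'   with attribute `split = FALSE` when refused).
#' @export
split_cluster4 <- function(scores) {
  if (is.data.frame(scores)) {
    id <- scores$anchor_id
    x <- scores$score
  } else {
    x <- as.numeric(scores)
    id <- if (!is.null(names(scores))) names(scores) else
      paste0("anchor_", seq_along(scores))
  }
  stop_if_not(length(x) >= 2, "need at least 2 anchors to split")
  if (length(unique(x)) == 1) {
    out <- tibble(anchor_id = id, score = x, sublabel = "4")
    attr(out, "split") <- FALSE
    warn("all scores identical: split refused")
    return(out)
  }
  grp <- split_1d_2means(x)
  out <- tibble(anchor_id = id, score = x,
                sublabel = ifelse(grp == 2L, "4a", "4b"))
  attr(out, "split") <- TRUE
  out
}

#' Nucleosome occupancy profile around oriented anchors
#'
#' Each fragment contributes coverage on the `2 * halfwidth + 1`
#' inclusive bases around its midpoint (51 bases at the default 25),
#' accumulated in oriented offsets and summed over anchors. Telomeric
#' anchors are dropped.
#'
#' @param fs fragment tibble (MNase-seq style nucleosomal fragments).
#' @param anchors oriented anchor tibble.
#' @param W window half-width in bp (default 300).
#' @param halfwidth midpoint extension in bp (default 25).
#' @param telomeres optional telomere intervals.
#' @return tibble offset, occupancy with attribute `n_anchors_used`.
#' @export
nucleosome_profile <- function(fs, anchors, W = 300L, halfwidth = 25L,
                               telomeres = NULL) {
  fs <- check_fragments(fs)
  anchors <- check_anchors(anchors)
  drop <- in_telomere(anchors, telomeres)
  anchors <- anchors[!drop, ]
  mid <- fragment_midpoint(fs$start, fs$end)
  occ <- numeric(2L * W + 1L)
  for (i in seq_len(nrow(anchors))) {
    a <- anchors$position[i]
    k <- fs$chrom == anchors$chrom[i] &
      mid + halfwidth >= a - W & mid - halfwidth <= a + W
    if (!any(k)) next
    off <- oriented_offset(mid[k], a, anchors$orientation[i])
    lo <- pmax(off - halfwidth, -W)
    hi <- pmin(off + halfwidth, W)
    for (j in seq_along(lo)) {
      idx <- (lo[j] + W + 1L):(hi[j] + W + 1L)
      occ[idx] <- occ[idx] + 1
    }
  }
  out <- tibble(offset = (-W):W, occupancy = occ)
  attr(out, "n_anchors_used") <- nrow(anchors)
  out
}

#' Quantify nucleosome shifts between two conditions
#'
#' For each side window (-1 upstream, +1 downstream of the anchor in
#' oriented coordinates) the occupancy maximum is located before and
#' after; the reported shift is the change in distance to the anchor,
#' signed so that negative means the nucleosome moved toward the binding
#' site. Ties at the maximum are broken toward the anchor. A flat profile
#' in a side window yields an `NA` shift with a flag.
#'
#' @param before,after occupancy tibbles from [nucleosome_profile()] on
#'   the same window.
#' @param minus1_window,plus1_window inclusive oriented offset ranges
#'   searched for the -1 and +1 nucleosomes (defaults `c(-250, -50)` and
#'   `c(50, 250)`).
#' @return a `chromfrag_shift` tibble: side, pos_before, pos_after,
#'   shift, flag.
#' @export
nucleosome_shift <- function(before, after,
                             minus1_window = c(-250L, -50L),
                             plus1_window = c(50L, 250L)) {
  stop_if_not(identical(before$offset, after$offset),
              "`before` and `after` must share the same window")
  peak_pos <- function(profile, win) {
    k <- profile$offset >= win[1] & profile$offset <= win[2]
    if (!any(k) || diff(range(profile$occupancy[k])) == 0) {
      return(NA_integer_)
    }
    o <- profile$offset[k]
    v <- profile$occupancy[k]
    cand <- o[v == max(v)]
    cand[which.min(abs(cand))]  # tie toward the anchor
  }
  one_side <- function(side, win) {
    pb <- peak_pos(before, win)
    pa <- peak_pos(after, win)
    if (is.na(pb) || is.na(pa)) {
      return(tibble(side = side, pos_before = pb, pos_after = pa,
                    shift = NA_real_, flag = "flat_profile"))
    }
    tibble(side = side, pos_before = pb, pos_after = pa,
           shift = -(abs(pb) - abs(pa)), flag = NA_character_)
  }
  out <- dplyr::bind_rows(one_side("minus1", minus1_window),
                          one_side("plus1", plus1_window))
  class(out) <- c("chromfrag_shift", class(out))
  out
}

#' @method tidy chromfrag_shift
#' @export
tidy.chromfrag_shift <- function(x, ...) {
  tibble(side = x$side, pos_before = x$pos_before, pos_after = x$pos_after,
         shift = x$shift, flag = x$flag)
}
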