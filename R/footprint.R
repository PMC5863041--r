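#' Stack fragment 5' and 3' ends around oriented anchors
#'
#' Each fragment overlapping `[anchor - W, anchor + W]` contributes its
#' two inclusive end bases: the 5' end (`start`) and the 3' end
#' (`end - 1`, the last covered base), mapped to oriented offsets. For
#' minus-oriented anchors the coordinate axis flips and the two ends swap
#' roles, so the "5'" profile is always the motif-upstream boundary.
#' Ends falling outside the window are clipped; within the window both
#' count vectors sum to the number of in-window ends.
#'
#' @param fs fragment tibble.
#' @param anchors anchor tibble (chrom, position, orientation).
#' @param W window half-width in bp.
#' @return tibble with columns `offset` (-W..W), `five_prime`,
#'   `three_prime`; attribute `n_fragments` = fragments contributing.
#' @export
end_profiles <- function(fs, anchors, W = 40L) {
  stop_if_not(W > 0, "`W` must be positive")
  fs <- check_fragments(fs)
  anchors <- check_anchors(anchors)
  offsets <- (-W):W
  five <- integer(2L * W + 1L)
  three <- integer(2L * W + 1L)
  n_frag <- 0L
  for (i in seq_len(nrow(anchors))) {
    a <- anchors$position[i]
    x <- fs[fs$chrom == anchors$chrom[i] &
              fs$start <= a + W & fs$end - 1L >= a - W, ]
    if (nrow(x) == 0) next
    n_frag <- n_frag + nrow(x)
    if (anchors$orientation[i] == "+") {
      o5 <- x$start - a
      o3 <- (x$end - 1L) - a
    } else {
      o5 <- a - (x$end - 1L)
      o3 <- a - x$start
    }
    k5 <- o5 >= -W & o5 <= W
    k3 <- o3 >= -W & o3 <= W
    five <- five + tabulate(o5[k5] + W + 1L, nbins = 2L * W + 1L)
    three <- three + tabulate(o3[k3] + W + 1L, nbins = 2L * W + 1L)
  }
  out <- tibble(offset = offsets, five_prime = five, three_prime = three)
  attr(out, "n_fragments") <- n_frag
  class(out) <- c("chromfrag_end_profiles", class(out))
  out
}

#' Estimate the protected footprint width from stacked fragment ends
#'
#' The left boundary is the modal 5'-end offset in `[-flank, 0)`, the
#' right boundary the modal 3'-end offset in `[0, flank]`; width is the
#' inclusive base count `R - L + 1`. Argmax ties are broken toward the
#' anchor.
#'
#' @param ep an [end_profiles()] result.
#' @param flank search half-width in bp (default 40).
#' @return list with `width`, `left`, `right` (boundary offsets).
#' @export
estimate_footprint_width <- function(ep, flank = 40L) {
  stop_if_not(all(c("offset", "five_prime", "three_prime") %in% names(ep)),
              "`ep` must come from end_profiles()")
  left_win <- ep$offset >= -flank & ep$offset < 0
  right_win <- ep$offset >= 0 & ep$offset <= flank
  if (!any(left_win) || !any(right_win) ||
      sum(ep$five_prime[left_win]) == 0 ||
      sum(ep$three_prime[right_win]) == 0) {
    abort("insufficient data: a flank window holds no fragment ends")
  }
  lo <- ep$offset[left_win]
  lc <- ep$five_prime[left_win]
  L <- max(lo[lc == max(lc)])      # tie toward the anchor (largest offset)
  ro <- ep$offset[right_win]
  rc <- ep$three_prime[right_win]
  R <- min(ro[rc == max(rc)])      # tie toward the anchor (smallest offset)
  list(width = R - L + 1L, left = L, right = R)
}

#' Meta-profile of coverage around oriented anchors
#'
#' Coverage in `[anchor - W, anchor + W]` is flipped for minus-oriented
#' anchors and summed over anchors.
#'
#' @param x fragment tibble (coverage computed internally) or a
#'   per-chromosome coverage list from [coverage_track()] input.
#' @param anchors anchor tibble.
#' @param W window half-width in bp.
#' @return tibble `offset`, `coverage`.
#' @export
metagene <- function(x, anchors, W = 500L) {
  anchors <- check_anchors(anchors)
  cov <- if (is.data.frame(x)) coverage_rle(check_fragments(x)) else x
  total <- numeric(2L * W + 1L)
  for (i in seq_len(nrow(anchors))) {
    a <- anchors$position[i]
    v <- rle_window(cov[[anchors$chrom[i]]], a - W, a + W)
    if (anchors$orientation[i] == "-") v <- rev(v)
    total <- total + v
  }
  tibble(offset = (-W):W, coverage = total)
}
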