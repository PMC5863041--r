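# Internal helpers shared across modules. All coordinates are 0-based,
# half-open (BED convention); fragment length = end - start.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

#' Midpoint of a fragment (floor of the mean of inclusive end coordinates)
#'
#' For a fragment `[start, end)` the inclusive base positions are `start`
#' and `end - 1`; the midpoint is `floor((start + end - 1) / 2)`. Even-length
#' fragments are assigned the left of the two central bases.
#' @param start,end integer vectors, 0-based half-open.
#' @return integer vector of midpoints.
#' @keywords internal
fragment_midpoint <- function(start, end) {
  as.integer(floor((start + end - 1) / 2))
}

# Oriented offset of a genomic position relative to an anchor: positive
# offsets point downstream of the anchor in the anchor's orientation.
oriented_offset <- function(pos, anchor_pos, orientation) {
  if (length(orientation) == 1L) {
    if (orientation == "+") pos - anchor_pos else anchor_pos - pos
  } else {
    ifelse(orientation == "+", pos - anchor_pos, anchor_pos - pos)
  }
}

check_anchors <- function(anchors) {
  stop_if_not(is.data.frame(anchors) &&
                all(c("chrom", "position", "orientation") %in% names(anchors)),
              "`anchors` must have columns chrom, position, orientation")
  stop_if_not(all(anchors$orientation %in% c("+", "-")),
              "anchor orientation must be '+' or '-'")
  anchors <- as_tibble(anchors)
  if (!"anchor_id" %in% names(anchors)) {
    anchors$anchor_id <- paste0("anchor_", seq_len(nrow(anchors)))
  }
  anchors
}

check_fragments <- function(fs) {
  stop_if_not(is.data.frame(fs) &&
                all(c("chrom", "start", "end") %in% names(fs)),
              "fragments must have columns chrom, start, end")
  stop_if_not(all(fs$end > fs$start), "fragment end must exceed start")
  as_tibble(fs)
}

# Per-chromosome coverage as an IRanges RleList-like named list of Rle,
# indexed from genomic position 0 (Rle index i <-> position i - 1).
coverage_rle <- function(fs, width_by_chrom = NULL) {
  fs <- check_fragments(fs)
  chroms <- unique(fs$chrom)
  out <- lapply(chroms, function(ch) {
    x <- fs[fs$chrom == ch, ]
    w <- if (!is.null(width_by_chrom) && ch %in% names(width_by_chrom)) {
      width_by_chrom[[ch]]
    } else {
      max(x$end)
    }
    IRanges::coverage(IRanges::IRanges(start = x$start + 1L, end = x$end),
                      width = w)
  })
  names(out) <- chroms
  out
}

# Extract coverage over inclusive 0-based positions [lo, hi] from an Rle,
# zero-padded outside the Rle's support.
rle_window <- function(rle, lo, hi) {
  n <- hi - lo + 1L
  out <- numeric(n)
  if (is.null(rle)) return(out)
  len <- length(rle)
  from <- max(lo, 0L)
  to <- min(hi, len - 1L)
  if (from > to) return(out)
  vals <- as.numeric(S4Vectors::window(rle, start = from + 1L, end = to + 1L))
  out[(from - lo + 1L):(to - lo + 1L)] <- vals
  out
}

# Telomere membership of anchor positions; telomeres is a tibble
# (chrom, start, end), half-open. Returns a logical vector.
in_telomere <- function(anchors, telomeres) {
  if (is.null(telomeres) || nrow(telomeres) == 0) {
    return(rep(FALSE, nrow(anchors)))
  }
  purrr::map_lgl(seq_len(nrow(anchors)), function(i) {
    t <- telomeres[telomeres$chrom == anchors$chrom[i], ]
    any(t$start <= anchors$position[i] & anchors$position[i] < t$end)
  })
}
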