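#' Plot a V-matrix as a density heatmap
#'
#' Fragment midpoint offset on x, fragment length on y; darker tiles mark
#' higher fragment density (the field's usual V-plot rendering).
#'
#' @param x a `chromfrag_vmatrix`.
#' @param trans count transform for the fill scale (default `"sqrt"`).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot chromfrag_vmatrix
#' @export
autoplot.chromfrag_vmatrix <- function(x, trans = "sqrt", ...) {
  d <- tidy(x)
  ggplot2::ggplot(d, ggplot2::aes(.data$offset, .data$length,
                                  fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 trans = trans) +
    ggplot2::labs(x = "midpoint offset from anchor (bp)",
                  y = "fragment length (bp)", fill = "fragments") +
    ggplot2::theme_minimal()
}

#' Plot stacked 5'/3' fragment-end profiles
#'
#' @param ep an [end_profiles()] result.
#' @return a ggplot object; vertical lines would mark estimated
#'   boundaries if added by the caller.
#' @export
plot_end_profiles <- function(ep) {
  d <- tidyr::pivot_longer(as_tibble(ep), c("five_prime", "three_prime"),
                           names_to = "end", values_to = "count")
  d$end <- factor(d$end, levels = c("five_prime", "three_prime"),
                  labels = c("5' ends", "3' ends"))
  ggplot2::ggplot(d, ggplot2::aes(.data$offset, .data$count,
                                  colour = .data$end)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c("5' ends" = "#2166ac",
                                            "3' ends" = "#762a83")) +
    ggplot2::labs(x = "offset from motif center (bp)", y = "end count",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot K-means centroid length profiles
#'
#' One line per canonical cluster over the 21 10-bp length bins.
#'
#' @param cl a [cluster_profiles()] result.
#' @return a ggplot object.
#' @export
plot_cluster_centroids <- function(cl) {
  lo <- length_bin_edges[-length(length_bin_edges)]
  d <- purrr::map(seq_len(cl$K), function(k) {
    tibble(cluster = factor(k), length = lo + 5L,
           fraction = as.numeric(cl$centroids[k, ]))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(.data$length, .data$fraction,
                                  colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "fragment length (bp, bin center)",
                  y = "fraction of fragments", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot a strand-split nascent-transcription profile
#'
#' Sense coverage up, antisense down, the usual divergent-transcription
#' rendering.
#'
#' @param dp a [netseq_coverage()] tibble.
#' @return a ggplot object.
#' @export
plot_directional_profile <- function(dp) {
  d <- tibble(offset = rep(dp$offset, 2),
              coverage = c(dp$sense, -dp$antisense),
              strand = rep(c("sense", "antisense"), each = nrow(dp)))
  ggplot2::ggplot(d, ggplot2::aes(.data$offset, .data$coverage,
                                  fill = .data$strand)) +
    ggplot2::geom_area(position = "identity") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "offset from binding site (bp)",
                  y = "3'-end coverage (sense up / antisense down)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot nucleosome occupancy before and after depletion
#'
#' @param before,after [nucleosome_profile()] tibbles on the same window.
#' @return a ggplot object.
#' @export
plot_nucleosome_profiles <- function(before, after) {
  d <- dplyr::bind_rows(
    dplyr::mutate(before, condition = "intact"),
    dplyr::mutate(after, condition = "depleted"))
  ggplot2::ggplot(d, ggplot2::aes(.data$offset, .data$occupancy,
                                  colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from binding site (bp)",
                  y = "nucleosome occupancy", colour = NULL) +
    ggplot2::theme_minimal()
}
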