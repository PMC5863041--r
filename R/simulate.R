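#' Simulation parameters for the synthetic chromatin generator
#'
#' Bundles every knob of the promoter-architecture simulator. The generator
#' emits fragments from a four-component mixture per binding site:
#'
#' * `tf_only` — short fragments spanning the factor-protected region
#'   (`2 * protected_halfwidth` bp, default a 30-bp footprint) plus a
#'   per-end outward overhang drawn as `round(|Normal(0, boundary_noise_sd
#'   / mnase_level)|)`. Heavier digestion (larger `mnase_level`) trims the
#'   overhang, sharpening the footprint boundaries.
#' * `cobound` — long fragments protected by the factor together with one
#'   adjacent nucleosome; length is truncated-normal
#'   (`cobound_length_mean`, `cobound_length_sd`) on
#'   `cobound_length_range` (default 160-220 bp), placed on the TSS-distal
#'   side of the motif with probability `distal_side_prob` for the site's
#'   class.
#' * `midfrag` — mid-length (~150 bp) weakly protected fragments centered
#'   on the motif whose mixture weight decays as `1 / mnase_level`, so they
#'   nearly vanish under heavy digestion.
#' * `nucleosomal` — phased nucleosome-sized fragments at the -1/+1 dyad
#'   positions flanking the nucleosome-depleted region.
#'
#' @param n_sites_per_class integer; binding sites simulated per promoter
#'   class (classes C1, C2, C3, C4a, C4b).
#' @param fragments_per_site integer; ChIP fragments emitted per site.
#' @param mnase_level positive real; relative digestion level on the
#'   1/9/27 scale used throughout. Default 1 (light digestion, the
#'   condition used for short-read peak reconstruction).
#' @param boundary_noise_sd non-negative real (bp); scale of the per-end
#'   outward overhang at unit MNase level.
#' @param protected_halfwidth integer bp; half-width of the
#'   factor-protected region (default 15, a 30-bp footprint).
#' @param nucleosome_length integer bp (default 147).
#' @param cobound_length_mean,cobound_length_sd real bp (defaults 190/12).
#' @param cobound_length_range length-2 numeric; truncation bounds for
#'   co-bound fragment lengths (default `c(160, 220)`).
#' @param midfrag_weight_at_unit_mnase real in `[0, 1]`; global multiplier
#'   on the mid-length mixture component at `mnase_level = 1`.
#' @param distal_side_prob named numeric; probability that a co-bound
#'   fragment covers the TSS-distal (-1) nucleosome, per class
#'   (default C3 = 0.5, C4a = C4b = 0.9).
#' @param tss_distance integer bp; distance from motif center to the TSS
#'   along the gene strand (default 120).
#' @param seed integer RNG seed; every generator is deterministic given
#'   the parameter set and seed.
#' @return a `chromfrag_sim_params` list.
#' @examples
#' p <- sim_params(n_sites_per_class = 5, fragments_per_site = 50)
#' panel <- build_site_panel(p)
#' @export
sim_params <- function(n_sites_per_class = 50,
                       fragments_per_site = 200,
                       mnase_level = 1,
                       boundary_noise_sd = 12,
                       protected_halfwidth = 15L,
                       nucleosome_length = 147L,
                       cobound_length_mean = 190,
                       cobound_length_sd = 12,
                       cobound_length_range = c(160, 220),
                       midfrag_weight_at_unit_mnase = 1,
                       distal_side_prob = c(C3 = 0.5, C4a = 0.9, C4b = 0.9),
                       tss_distance = 120L,
                       seed = 1L) {
  stop_if_not(mnase_level > 0, "`mnase_level` must be positive")
  stop_if_not(boundary_noise_sd >= 0, "`boundary_noise_sd` must be >= 0")
  stop_if_not(protected_halfwidth >= 1, "`protected_halfwidth` must be >= 1")
  stop_if_not(nucleosome_length > 0 && cobound_length_mean > 0,
              "lengths must be positive")
  stop_if_not(midfrag_weight_at_unit_mnase >= 0 &&
                midfrag_weight_at_unit_mnase <= 1,
              "`midfrag_weight_at_unit_mnase` must be in [0, 1]")
  stop_if_not(all(distal_side_prob >= 0 & distal_side_prob <= 1),
              "`distal_side_prob` entries must be in [0, 1]")
  stop_if_not(length(cobound_length_range) == 2 &&
                cobound_length_range[1] < cobound_length_range[2],
              "`cobound_length_range` must be increasing bounds")
  structure(
    list(n_sites_per_class = as.integer(n_sites_per_class),
         fragments_per_site = as.integer(fragments_per_site),
         mnase_level = mnase_level,
         boundary_noise_sd = boundary_noise_sd,
         protected_halfwidth = as.integer(protected_halfwidth),
         nucleosome_length = as.integer(nucleosome_length),
         cobound_length_mean = cobound_length_mean,
         cobound_length_sd = cobound_length_sd,
         cobound_length_range = cobound_length_range,
         midfrag_weight_at_unit_mnase = midfrag_weight_at_unit_mnase,
         distal_side_prob = distal_side_prob,
         tss_distance = as.integer(tss_distance),
         seed = as.integer(seed)),
    class = "chromfrag_sim_params")
}

site_classes <- c("C1", "C2", "C3", "C4a", "C4b")

# Mixture weight templates over {tf_only, cobound, midfrag, nucleosomal}
# at unit MNase, before the midfrag 1/mnase scaling and renormalization.
# C1: factor-only; C2: continuum of factor-only + mid-length; C3: bimodal,
# co-bound fragments on either side; C4a/C4b: bimodal, co-bound dominated
# with strong TSS-distal (-1 nucleosome) preference.
class_weight_templates <- function() {
  rbind(
    C1  = c(tf_only = 0.75, cobound = 0.00, midfrag = 0.10, nucleosomal = 0.15),
    C2  = c(tf_only = 0.40, cobound = 0.00, midfrag = 0.45, nucleosomal = 0.15),
    C3  = c(tf_only = 0.45, cobound = 0.35, midfrag = 0.05, nucleosomal = 0.15),
    C4a = c(tf_only = 0.25, cobound = 0.55, midfrag = 0.05, nucleosomal = 0.15),
    C4b = c(tf_only = 0.25, cobound = 0.55, midfrag = 0.05, nucleosomal = 0.15))
}

# Effective mixture weights for one class at the given MNase level.
effective_weights <- function(class_label, params) {
  w <- class_weight_templates()[class_label, ]
  w["midfrag"] <- w["midfrag"] *
    params$midfrag_weight_at_unit_mnase / params$mnase_level
  w / sum(w)
}

#' Build a panel of simulated binding sites with known ground truth
#'
#' Lays out `5 * n_sites_per_class` non-overlapping binding sites (classes
#' C1, C2, C3, C4a, C4b, shuffled) on one synthetic chromosome with at
#' least 2 kb between neighbouring motif centers. Each site carries a
#' motif center and strand, a TSS placed `tss_distance` bp downstream of
#' the motif along the gene strand, -1/+1 nucleosome dyad positions
#' flanking the nucleosome-depleted region (the C4b -1 dyad is pushed
#' against the protected region), and the class mixture weights.
#'
#' @param params a [sim_params()] object.
#' @param chrom_size optional integer; fail if the requested sites do not
#'   fit in a chromosome of this size.
#' @return a `chromfrag_site_panel`: list with `sites` (tibble),
#'   `chrom_sizes` (tibble chrom/size) and `telomeres` (tibble
#'   chrom/start/end, the outer 1 kb of the chromosome).
#' @export
build_site_panel <- function(params, chrom_size = NULL) {
  stop_if_not(inherits(params, "chromfrag_sim_params"),
              "`params` must come from sim_params()")
  n <- params$n_sites_per_class * length(site_classes)
  withr::with_seed(params$seed, {
    jitter <- sample(0:200, n, replace = TRUE)
    centers <- 3000L + (seq_len(n) - 1L) * 2400L + jitter
    labels <- sample(rep(site_classes, each = params$n_sites_per_class))
    motif_strand <- sample(c("+", "-"), n, replace = TRUE)
    tss_strand <- sample(c("+", "-"), n, replace = TRUE)
  })
  size_needed <- max(centers) + 3000L
  if (!is.null(chrom_size)) {
    if (chrom_size < size_needed) {
      abort(sprintf(
        "chromosome of size %d too small for %d sites (need %d bp)",
        chrom_size, n, size_needed))
    }
    size_needed <- as.integer(chrom_size)
  }
  s <- ifelse(tss_strand == "+", 1L, -1L)  # genomic direction toward the gene
  h <- params$protected_halfwidth
  d_minus <- ifelse(labels == "C4b", h + 74L, 130L)  # C4b: -1 abuts the motif
  sites <- tibble(
    site_id = sprintf("site_%03d", seq_len(n)),
    chrom = "chrS",
    motif_center = as.integer(centers),
    motif_strand = motif_strand,
    tss_offset = as.integer(s * params$tss_distance),
    tss_strand = tss_strand,
    class_label = labels,
    minus1_dyad = as.integer(centers - s * d_minus),
    plus1_dyad = as.integer(centers + s * 140L))
  w <- t(vapply(sites$class_label,
                function(cl) effective_weights(cl, params), numeric(4)))
  sites$w_tf_only <- w[, "tf_only"]
  sites$w_cobound <- w[, "cobound"]
  sites$w_midfrag <- w[, "midfrag"]
  sites$w_nucleosomal <- w[, "nucleosomal"]
  structure(
    list(sites = sites,
         chrom_sizes = tibble(chrom = "chrS", size = size_needed),
         telomeres = tibble(chrom = "chrS",
                            start = c(0L, size_needed - 1000L),
                            end = c(1000L, size_needed))),
    class = "chromfrag_site_panel")
}

#' @export
print.chromfrag_site_panel <- function(x, ...) {
  cat(sprintf("<site panel: %d sites on %s (%d bp)>\n",
              nrow(x$sites), x$chrom_sizes$chrom[1], x$chrom_sizes$size[1]))
  print(table(x$sites$class_label))
  invisible(x)
}

# Truncated normal sampler via inverse-CDF; exact, vectorized.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate ChIP fragments from a site panel
#'
#' Draws `fragments_per_site` fragments per site from the site's mixture
#' over fragment classes (see [sim_params()]). Every fragment carries its
#' generating class and site in the `name` field (`site_id:class`) so
#' downstream classification can be scored against ground truth.
#'
#' @param panel a [build_site_panel()] result.
#' @param params the [sim_params()] used to build the panel.
#' @return tibble with columns chrom, start, end, name, score, strand,
#'   site_id, frag_class, site_class (0-based half-open intervals).
#' @export
simulate_chip_fragments <- function(panel, params) {
  stop_if_not(inherits(panel, "chromfrag_site_panel"),
              "`panel` must come from build_site_panel()")
  stop_if_not(params$mnase_level > 0, "`mnase_level` must be positive")
  sd_eff <- params$boundary_noise_sd / params$mnase_level
  h <- params$protected_halfwidth
  lo <- params$cobound_length_range[1]
  up <- params$cobound_length_range[2]
  withr::with_seed(params$seed + 1L, {
    frags <- purrr::map(seq_len(nrow(panel$sites)), function(i) {
      site <- panel$sites[i, ]
      m <- params$fragments_per_site
      w <- effective_weights(site$class_label, params)  # honours mnase_level
      cls <- sample(c("tf_only", "cobound", "midfrag", "nucleosomal"), m,
                    replace = TRUE, prob = w)
      c0 <- site$motif_center
      s <- sign(site$tss_offset)
      start <- integer(m); end <- integer(m)

      k <- cls == "tf_only"
      if (any(k)) {
        o5 <- round(abs(stats::rnorm(sum(k), 0, sd_eff)))
        o3 <- round(abs(stats::rnorm(sum(k), 0, sd_eff)))
        start[k] <- c0 - h - o5
        end[k] <- c0 + h + o3
      }
      k <- cls == "cobound"
      if (any(k)) {
        p_distal <- params$distal_side_prob[[site$class_label]]
        len <- pmin(pmax(round(rtruncnorm(sum(k), params$cobound_length_mean,
                                          params$cobound_length_sd, lo, up)),
                         lo), up)
        distal <- stats::runif(sum(k)) < p_distal
        d <- ifelse(distal, -s, s)  # genomic direction of the covered nucleosome
        start[k] <- ifelse(d > 0, c0 - h, c0 + h - len)
        end[k] <- ifelse(d > 0, c0 - h + len, c0 + h)
      }
      k <- cls == "midfrag"
      if (any(k)) {
        len <- pmax(round(stats::rnorm(sum(k), 150, 10)), 40)
        center <- c0 + round(stats::rnorm(sum(k), 0, 10))  # loosely positioned
        start[k] <- center - floor(len / 2)
        end[k] <- start[k] + len
      }
      k <- cls == "nucleosomal"
      if (any(k)) {
        dyad <- ifelse(stats::runif(sum(k)) < 0.5,
                       site$minus1_dyad, site$plus1_dyad) +
          round(stats::rnorm(sum(k), 0, 8))
        len <- pmax(round(stats::rnorm(sum(k), params$nucleosome_length, 5)), 80)
        start[k] <- dyad - floor(len / 2)
        end[k] <- start[k] + len
      }
      tibble(chrom = site$chrom, start = as.integer(start),
             end = as.integer(end),
             name = paste0(site$site_id, ":", cls),
             score = 0L, strand = ".",
             site_id = site$site_id, frag_class = cls,
             site_class = site$class_label)
    })
  })
  dplyr::bind_rows(frags)
}

#' Simulate strand-specific nascent-transcription (NET-seq) 3' ends
#'
#' Per site, each read is sense (on the gene strand, 3' end downstream of
#' the TSS) or antisense, with class-dependent antisense structure:
#' C1 initiates symmetrically on both sides of the motif (antisense
#' probability exactly 1/2); C2/C3 show reduced divergent initiation;
#' C4a emits short aborted antisense transcripts whose 3' ends pile up
#' within 50 bp upstream of the motif center; C4b instead initiates
#' antisense transcription from an upstream NDR ~350 bp upstream of the
#' motif, leaving the motif-proximal upstream window empty.
#'
#' @param panel a site panel.
#' @param reads_per_site integer reads per site.
#' @param seed integer seed.
#' @param aborted_weight probability that a C4a read is an aborted
#'   upstream transcript (default 0.3); set 0 to switch them off.
#' @param upstream_ndr_weight probability that a C4b read initiates from
#'   the upstream NDR (default 0.3).
#' @param antisense_prob named antisense probabilities for C1/C2/C3.
#' @return tibble chrom, pos (0-based 3' base), strand, site_id,
#'   read_class, site_class.
#' @export
simulate_netseq_reads <- function(panel, reads_per_site, seed = 1L,
                                  aborted_weight = 0.3,
                                  upstream_ndr_weight = 0.3,
                                  antisense_prob = c(C1 = 0.5, C2 = 0.35,
                                                     C3 = 0.35)) {
  stop_if_not(inherits(panel, "chromfrag_site_panel"),
              "`panel` must come from build_site_panel()")
  stop_if_not(reads_per_site >= 1, "`reads_per_site` must be >= 1")
  stop_if_not(aborted_weight >= 0 && aborted_weight <= 1 &&
                upstream_ndr_weight >= 0 && upstream_ndr_weight <= 1,
              "weights must be in [0, 1]")
  withr::with_seed(as.integer(seed), {
    reads <- purrr::map(seq_len(nrow(panel$sites)), function(i) {
      site <- panel$sites[i, ]
      m <- reads_per_site
      c0 <- site$motif_center
      s <- sign(site$tss_offset)
      tss <- c0 + site$tss_offset
      anti_strand <- if (site$tss_strand == "+") "-" else "+"
      cl <- site$class_label
      body_off <- function(k) sample(30:250, k, replace = TRUE)

      if (cl %in% c("C1", "C2", "C3")) {
        anti <- stats::runif(m) < antisense_prob[[cl]]
        pos <- ifelse(anti, c0 - s * (site$tss_offset * s + body_off(m)),
                      tss + s * body_off(m))
        rc <- ifelse(anti, "antisense", "sense")
      } else if (cl == "C4a") {
        anti <- stats::runif(m) < aborted_weight
        pos <- ifelse(anti, c0 - s * sample(1:50, m, replace = TRUE),
                      tss + s * body_off(m))
        rc <- ifelse(anti, "aborted", "sense")
      } else {  # C4b
        anti <- stats::runif(m) < upstream_ndr_weight
        pos <- ifelse(anti, c0 - s * (350 + sample(0:150, m, replace = TRUE)),
                      tss + s * body_off(m))
        rc <- ifelse(anti, "upstream_ndr", "sense")
      }
      tibble(chrom = site$chrom, pos = as.integer(pos),
             strand = ifelse(anti, anti_strand, site$tss_strand),
             site_id = site$site_id, read_class = rc, site_class = cl)
    })
  })
  dplyr::bind_rows(reads)
}

#' Simulate nucleosome (MNase-seq) fragments, optionally remodeler-depleted
#'
#' Emits nucleosome-sized fragments at each site's -1 and +1 dyads. Under
#' remodeler depletion the classes respond differently: C1 (and C2/C3)
#' dyads both shift `shift_bp` toward the motif (loss of NDR-maintaining
#' remodeling); C4a keeps its -1 dyad fixed ("locked") while the +1 dyad
#' shifts toward the motif; C4b's -1 dyad slides `shift_bp` away from the
#' motif (it is normally "pushed" against the factor), +1 toward it.
#'
#' @param panel a site panel.
#' @param depleted logical; simulate the remodeler-depleted condition.
#' @param shift_bp non-negative integer shift applied on depletion.
#' @param seed integer seed.
#' @param fragments_per_site integer fragments per site (default 1000).
#' @param dyad_jitter_sd real; positional jitter of fragment centers
#'   around the dyad (default 8 bp).
#' @return fragment tibble as in [simulate_chip_fragments()], with
#'   `frag_class` in `{minus1, plus1}`.
#' @export
simulate_nucleosome_fragments <- function(panel, depleted = FALSE,
                                          shift_bp = 25L, seed = 1L,
                                          fragments_per_site = 1000L,
                                          dyad_jitter_sd = 8) {
  stop_if_not(inherits(panel, "chromfrag_site_panel"),
              "`panel` must come from build_site_panel()")
  stop_if_not(shift_bp >= 0, "`shift_bp` must be >= 0")
  withr::with_seed(as.integer(seed), {
    frags <- purrr::map(seq_len(nrow(panel$sites)), function(i) {
      site <- panel$sites[i, ]
      s <- sign(site$tss_offset)
      cl <- site$class_label
      minus1 <- site$minus1_dyad
      plus1 <- site$plus1_dyad
      if (depleted) {
        # toward the motif: -1 sits at motif - s*d, +1 at motif + s*d
        if (cl %in% c("C1", "C2", "C3")) {
          minus1 <- minus1 + s * shift_bp
          plus1 <- plus1 - s * shift_bp
        } else if (cl == "C4a") {
          plus1 <- plus1 - s * shift_bp        # -1 locked in place
        } else {                               # C4b: -1 pushed back out
          minus1 <- minus1 - s * shift_bp
          plus1 <- plus1 - s * shift_bp
        }
      }
      m <- fragments_per_site
      side <- ifelse(stats::runif(m) < 0.5, "minus1", "plus1")
      dyad <- ifelse(side == "minus1", minus1, plus1) +
        round(stats::rnorm(m, 0, dyad_jitter_sd))
      len <- pmax(round(stats::rnorm(m, 147, 5)), 80)
      start <- as.integer(dyad - floor(len / 2))
      tibble(chrom = site$chrom, start = start,
             end = as.integer(start + len),
             name = paste0(site$site_id, ":", side),
             score = 0L, strand = ".",
             site_id = site$site_id, frag_class = side, site_class = cl)
    })
  })
  dplyr::bind_rows(frags)
}

#' Anchors (oriented alignment points) from a site panel
#'
#' @param panel a site panel.
#' @param orient_by `"tss"` (anchor at the motif center, oriented by gene
#'   direction so positive offsets point toward the TSS) or `"motif"`
#'   (oriented by motif strand).
#' @return anchor tibble: chrom, position, orientation, anchor_id,
#'   site_class.
#' @export
panel_anchors <- function(panel, orient_by = c("tss", "motif")) {
  orient_by <- match.arg(orient_by)
  s <- panel$sites
  tibble(chrom = s$chrom, position = s$motif_center,
         orientation = if (orient_by == "tss") s$tss_strand else s$motif_strand,
         anchor_id = s$site_id, site_class = s$class_label)
}
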