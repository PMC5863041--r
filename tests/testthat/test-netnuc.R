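anchor1 <- function(pos, orientation = "+", chrom = "chrI") {
  tibble::tibble(chrom = chrom, position = pos, orientation = orientation,
                 anchor_id = "a1")
}

test_that("3' ends are extended 20 bp in the 5' direction over 21
           inclusive bases", {
  reads <- tibble::tibble(chrom = "chrI", pos = 100L, strand = "+")
  dp <- netseq_coverage(reads, anchor1(100L), W = 50L)
  covered <- dp$offset[dp$sense > 0]
  expect_equal(range(covered), c(-20L, 0L))   # genomic [80, 100]
  expect_equal(sum(dp$sense), 21)
  expect_equal(sum(dp$antisense), 0)
  # minus-strand read extends rightward; antisense vs a + anchor
  m <- tibble::tibble(chrom = "chrI", pos = 100L, strand = "-")
  dp <- netseq_coverage(m, anchor1(100L), W = 50L)
  expect_equal(range(dp$offset[dp$antisense > 0]), c(0L, 20L))
})

test_that("coverage mass is (extension + 1) per interior read and
           telomeric anchors are excluded", {
  panel <- tiny_panel(seed = 19L)
  reads <- simulate_netseq_reads(panel, 200L, seed = 19L)
  an <- panel_anchors(panel, "tss")
  dp <- netseq_coverage(reads, an, W = 1000L, telomeres = panel$telomeres)
  # every simulated read and its extension lie well inside +/-1000
  expect_equal(sum(dp$sense) + sum(dp$antisense), 21 * nrow(reads))
  expect_equal(attr(dp, "n_anchors_used"), nrow(an))
  # an anchor placed inside a telomere is dropped
  tel_anchor <- tibble::tibble(chrom = "chrS", position = 500L,
                               orientation = "+", anchor_id = "tel")
  dp2 <- netseq_coverage(reads, tel_anchor, W = 100L,
                         telomeres = panel$telomeres)
  expect_equal(attr(dp2, "n_anchors_used"), 0L)
  expect_equal(sum(dp2$sense) + sum(dp2$antisense), 0)
  expect_error(netseq_coverage(reads, an, extension = -1L), "extension")
})

test_that("aborted-transcript score counts motif-proximal antisense ends
           only and ignores the sense level", {
  an <- anchor1(1000L)
  sense <- tibble::tibble(chrom = "chrI", pos = 1100L + 1:50, strand = "+")
  expect_equal(aborted_transcript_score(sense, an)$score, 0)
  aborted <- tibble::tibble(chrom = "chrI", pos = 990L, strand = "-")
  far_anti <- tibble::tibble(chrom = "chrI", pos = 700L, strand = "-")
  r <- dplyr::bind_rows(sense, aborted, far_anti)
  got <- aborted_transcript_score(r, an)
  expect_equal(got$score, 1000 * 1 / 2)   # 1 of 2 antisense reads aborted
  # doubling the sense reads leaves the score unchanged
  r2 <- dplyr::bind_rows(r, sense)
  expect_equal(aborted_transcript_score(r2, an)$score, got$score)
  # no reads at all: flagged zero
  empty <- aborted_transcript_score(sense[0, ], an)
  expect_equal(empty$score, 0)
  expect_equal(empty$flag, "no_reads")
})

test_that("simulated locked sites score high, pushed sites near zero", {
  panel <- tiny_panel(seed = 37L)
  reads <- simulate_netseq_reads(panel, 500L, seed = 37L)
  an <- panel_anchors(panel, "tss")
  sc <- aborted_transcript_score(reads, an)
  sc$cls <- panel$sites$class_label[match(sc$anchor_id,
                                          panel$sites$site_id)]
  m4a <- mean(sc$score[sc$cls == "C4a"])
  m4b <- mean(sc$score[sc$cls == "C4b"])
  expect_gt(m4a, m4b)
  # Cohen's d (pooled within-group SD) well beyond 2
  sd_pooled <- sqrt(mean(c(stats::var(sc$score[sc$cls == "C4a"]),
                           stats::var(sc$score[sc$cls == "C4b"]))))
  expect_gt((m4a - m4b) / sd_pooled, 2)
})

test_that("1-D 2-means split matches brute-force optimal partitions", {
  got <- split_cluster4(c(a = 0, b = 0, c = 0, d = 5, e = 6, f = 7))
  expect_equal(got$sublabel, c("4b", "4b", "4b", "4a", "4a", "4a"))
  # brute-force oracle: minimize SSE over all 2-subset partitions
  brute <- function(x) {
    n <- length(x)
    best <- NULL; best_ss <- Inf
    for (mask in 1:(2^n - 2)) {
      g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
      ss <- sum((x[g] - mean(x[g]))^2) + sum((x[!g] - mean(x[!g]))^2)
      if (ss < best_ss - 1e-12) { best_ss <- ss; best <- g }
    }
    # normalize: TRUE = higher-mean group
    if (mean(x[best]) < mean(x[!best])) best <- !best
    best
  }
  withr::with_seed(8, {
    for (rep in 1:10) {
      x <- round(stats::runif(8, 0, 10), 2)
      if (length(unique(x)) == 1) next
      got <- split_cluster4(x)
      expect_equal(got$sublabel == "4a", unname(brute(x)))
    }
  })
  expect_warning(all0 <- split_cluster4(c(0, 0, 0)), "refused")
  expect_equal(unique(all0$sublabel), "4")
  expect_false(attr(all0, "split"))
})

test_that("simulated subcluster labels are recovered from NET-seq scores", {
  panel <- tiny_panel(seed = 41L)
  reads <- simulate_netseq_reads(panel, 500L, seed = 41L)
  an <- panel_anchors(panel, "tss")
  c4 <- an[an$site_class %in% c("C4a", "C4b"), ]
  sc <- aborted_transcript_score(reads, c4)
  sp <- split_cluster4(sc)
  truth <- panel$sites$class_label[match(sp$anchor_id,
                                         panel$sites$site_id)]
  agreement <- mean((sp$sublabel == "4a") == (truth == "C4a"))
  expect_gte(agreement, 0.9)
})

test_that("nucleosome profile extends midpoints by 25 bp each side", {
  fs <- tibble::tibble(chrom = "chrI", start = 100L, end = 160L)
  # center floor((100 + 159)/2) = 129 -> covered bases [104, 154]
  np <- nucleosome_profile(fs, anchor1(129L), W = 60L)
  covered <- np$offset[np$occupancy > 0]
  expect_equal(range(covered), c(-25L, 25L))
  expect_equal(sum(np$occupancy), 51)
  # mass conservation for interior fragments
  panel <- tiny_panel(seed = 43L)
  nuc <- simulate_nucleosome_fragments(panel, fragments_per_site = 100L,
                                       seed = 43L)
  an <- panel_anchors(panel, "tss")
  np <- nucleosome_profile(nuc, an, W = 400L)
  expect_equal(sum(np$occupancy), 51 * nrow(nuc))
})

test_that("profile maxima sit at the configured dyads", {
  p <- sim_params(n_sites_per_class = 10L, seed = 47L)
  panel <- build_site_panel(p)
  nuc <- simulate_nucleosome_fragments(panel, fragments_per_site = 2000L,
                                       seed = 47L)
  # C1 sites only: dyads at oriented -130 and +140
  an <- panel_anchors(panel, "tss")
  an <- an[an$site_class == "C1", ]
  np <- nucleosome_profile(nuc[nuc$site_class == "C1", ], an, W = 300L)
  up <- np[np$offset < 0, ]
  down <- np[np$offset > 0, ]
  expect_lte(abs(up$offset[which.max(up$occupancy)] + 130L), 2L)
  expect_lte(abs(down$offset[which.max(down$occupancy)] - 140L), 2L)
})

test_that("shift quantification recovers configured shifts and the
           locked -1 nucleosome", {
  panel <- build_site_panel(sim_params(n_sites_per_class = 10L, seed = 53L))
  before <- simulate_nucleosome_fragments(panel, FALSE, shift_bp = 25L,
                                          seed = 53L,
                                          fragments_per_site = 500L)
  after <- simulate_nucleosome_fragments(panel, TRUE, shift_bp = 25L,
                                         seed = 53L,
                                         fragments_per_site = 500L)
  an <- panel_anchors(panel, "tss")
  shift_for <- function(cls) {
    ga <- an[an$site_class == cls, ]
    nucleosome_shift(
      nucleosome_profile(before[before$site_class == cls, ], ga),
      nucleosome_profile(after[after$site_class == cls, ], ga))
  }
  s1 <- shift_for("C1")
  expect_lte(abs(s1$shift[s1$side == "minus1"] + 25), 3)
  expect_lte(abs(s1$shift[s1$side == "plus1"] + 25), 3)
  s4a <- shift_for("C4a")
  expect_lte(abs(s4a$shift[s4a$side == "minus1"]), 3)      # locked
  expect_lte(abs(s4a$shift[s4a$side == "plus1"] + 25), 3)
  s4b <- shift_for("C4b")
  expect_lte(abs(s4b$shift[s4b$side == "minus1"] - 25), 3)  # pushed back
  # identical profiles give zero shifts; flat windows are flagged
  np <- nucleosome_profile(before, an)
  s0 <- nucleosome_shift(np, np)
  expect_equal(s0$shift, c(0, 0))
  flat <- tibble::tibble(offset = -300:300, occupancy = 1)
  sf <- nucleosome_shift(flat, flat)
  expect_true(all(is.na(sf$shift)))
  expect_equal(unique(sf$flag), "flat_profile")
})
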