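test_that("site panel has the requested composition, spacing and bounds", {
  panel <- tiny_panel()
  expect_equal(nrow(panel$sites), 25L)
  expect_equal(unname(table(panel$sites$class_label)[c("C1", "C2", "C3",
                                                       "C4a", "C4b")]),
               rep(5L, 5), ignore_attr = TRUE)
  expect_false(anyDuplicated(panel$sites$site_id) > 0)
  # exhaustive pairwise spacing scan
  centers <- sort(panel$sites$motif_center)
  expect_true(min(diff(centers)) >= 2000)
  size <- panel$chrom_sizes$size[1]
  expect_true(all(panel$sites$motif_center > 0 &
                    panel$sites$motif_center < size))
  # mixture weights sum to one per site
  w <- panel$sites[, c("w_tf_only", "w_cobound", "w_midfrag",
                       "w_nucleosomal")]
  expect_equal(rowSums(as.matrix(w)), rep(1, 25), tolerance = 1e-12)
})

test_that("panel and fragment generation are deterministic given the seed", {
  p <- tiny_params(seed = 9L)
  expect_identical(build_site_panel(p), build_site_panel(p))
  panel <- build_site_panel(p)
  expect_identical(simulate_chip_fragments(panel, p),
                   simulate_chip_fragments(panel, p))
  expect_identical(simulate_netseq_reads(panel, 50, seed = 3L),
                   simulate_netseq_reads(panel, 50, seed = 3L))
  expect_identical(
    simulate_nucleosome_fragments(panel, FALSE, seed = 3L,
                                  fragments_per_site = 50L),
    simulate_nucleosome_fragments(panel, FALSE, seed = 3L,
                                  fragments_per_site = 50L))
})

test_that("fragment counts are conserved and classes are labelled", {
  p <- tiny_params()
  panel <- build_site_panel(p)
  fr <- simulate_chip_fragments(panel, p)
  expect_equal(nrow(fr), p$fragments_per_site * nrow(panel$sites))
  expect_true(all(fr$frag_class %in% c("tf_only", "cobound", "midfrag",
                                       "nucleosomal")))
  expect_true(all(fr$end > fr$start))
  expect_identical(fr$name, paste0(fr$site_id, ":", fr$frag_class))
})

test_that("co-bound fragments respect the truncation bounds and their
           length distribution matches the truncated normal", {
  p <- sim_params(n_sites_per_class = 5L, fragments_per_site = 4000L,
                  seed = 5L)
  panel <- build_site_panel(p)
  fr <- simulate_chip_fragments(panel, p)
  cb <- fr$end - fr$start
  cb <- cb[fr$frag_class == "cobound"]
  expect_true(length(cb) > 1e4)
  expect_true(all(cb >= 160 & cb <= 220))
  # KS distance against the closed-form truncated-normal CDF (the small
  # residual comes from rounding to integer lengths)
  trunc_cdf <- function(q) {
    (pnorm(q, 190, 12) - pnorm(160, 190, 12)) /
      (pnorm(220, 190, 12) - pnorm(160, 190, 12))
  }
  ks <- suppressWarnings(ks.test(cb, trunc_cdf))
  expect_lt(unname(ks$statistic), 0.05)
  mf <- (fr$end - fr$start)[fr$frag_class == "midfrag"]
  expect_equal(mean(mf), 150, tolerance = 0.02)
  expect_equal(sd(mf), 10, tolerance = 0.1)
})

test_that("co-bound fragments sit on the TSS-distal side with the
           configured probability", {
  p <- sim_params(n_sites_per_class = 2L, fragments_per_site = 2000L,
                  seed = 21L)
  panel <- build_site_panel(p)
  fr <- simulate_chip_fragments(panel, p)
  cb <- fr[fr$frag_class == "cobound" & fr$site_class %in% c("C4a", "C4b"), ]
  s <- panel$sites[match(cb$site_id, panel$sites$site_id), ]
  mid <- floor((cb$start + cb$end - 1) / 2)
  distal <- sign(mid - s$motif_center) == -sign(s$tss_offset)
  n <- nrow(cb)
  expect_gt(n, 1000)
  # binomial check: fraction within 3 SDs of 0.9
  expect_lt(abs(mean(distal) - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("mid-length fragments disappear as MNase digestion increases", {
  p1 <- sim_params(n_sites_per_class = 5L, fragments_per_site = 500L,
                   mnase_level = 1, seed = 8L)
  p27 <- sim_params(n_sites_per_class = 5L, fragments_per_site = 500L,
                    mnase_level = 27, seed = 8L)
  panel <- build_site_panel(p1)
  n_mid <- function(p) {
    fr <- simulate_chip_fragments(panel, p)
    len <- fr$end - fr$start
    sum(len >= 140 & len < 160)
  }
  expect_lt(n_mid(p27), n_mid(p1))
  # monotone decay of the effective mid-length weight with MNase level
  w <- vapply(c(1, 9, 27),
              function(m) {
                pm <- sim_params(mnase_level = m)
                chromfrag:::effective_weights("C2", pm)[["midfrag"]]
              }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("parameter validation rejects invalid settings", {
  expect_error(sim_params(mnase_level = 0), "mnase_level")
  expect_error(sim_params(mnase_level = -2), "mnase_level")
  expect_error(sim_params(midfrag_weight_at_unit_mnase = 1.5), "midfrag")
  expect_error(build_site_panel(tiny_params(), chrom_size = 5000),
               "too small")
})

test_that("NET-seq reads: C1 initiates symmetrically, C4 classes differ in
           upstream antisense structure", {
  p <- sim_params(n_sites_per_class = 4L, fragments_per_site = 100L,
                  seed = 31L)
  panel <- build_site_panel(p)
  reads <- simulate_netseq_reads(panel, reads_per_site = 1000L, seed = 31L)
  c1 <- reads[reads$site_class == "C1", ]
  n <- nrow(c1)
  n_anti <- sum(c1$read_class == "antisense")
  # |sense - antisense| within 3 binomial SDs of 0 at p = 1/2
  expect_lt(abs((n - n_anti) - n_anti), 3 * sqrt(n * 0.25) * 2)
  # C4a aborted 3' ends pile within 50 bp upstream of the motif center
  c4a <- reads[reads$site_class == "C4a" & reads$read_class == "aborted", ]
  s <- panel$sites[match(c4a$site_id, panel$sites$site_id), ]
  updist <- -sign(s$tss_offset) * (c4a$pos - s$motif_center)
  expect_true(all(updist >= 1 & updist <= 50))
  # with the aborted component switched off there are no antisense 3'
  # ends near the motif at C4 sites
  r0 <- simulate_netseq_reads(panel, 1000L, seed = 31L, aborted_weight = 0)
  c4 <- r0[r0$site_class %in% c("C4a", "C4b"), ]
  s <- panel$sites[match(c4$site_id, panel$sites$site_id), ]
  anti <- c4$strand != s$tss_strand
  updist <- -sign(s$tss_offset) * (c4$pos - s$motif_center)
  expect_equal(sum(anti & updist >= 0 & updist <= 50), 0L)
  # C4b upstream-NDR initiation sits ~350 bp upstream, not at the motif
  c4b <- reads[reads$site_class == "C4b" & reads$read_class == "upstream_ndr", ]
  s <- panel$sites[match(c4b$site_id, panel$sites$site_id), ]
  updist <- -sign(s$tss_offset) * (c4b$pos - s$motif_center)
  expect_true(all(updist >= 350))
})

test_that("nucleosome simulator implements locked and pushed -1 dyads", {
  panel <- tiny_panel(seed = 55L)
  before <- simulate_nucleosome_fragments(panel, FALSE, shift_bp = 25L,
                                          seed = 6L,
                                          fragments_per_site = 1000L)
  after <- simulate_nucleosome_fragments(panel, TRUE, shift_bp = 25L,
                                         seed = 6L,
                                         fragments_per_site = 1000L)
  mean_disp <- function(cls, side) {
    # displacement of mean fragment midpoint toward the motif, per site,
    # averaged over sites of the class
    ids <- panel$sites$site_id[panel$sites$class_label == cls]
    vapply(ids, function(id) {
      s <- panel$sites[panel$sites$site_id == id, ]
      mb <- with(before[before$site_id == id & before$frag_class == side, ],
                 mean(floor((start + end - 1) / 2)))
      ma <- with(after[after$site_id == id & after$frag_class == side, ],
                 mean(floor((start + end - 1) / 2)))
      # positive = toward the motif
      (abs(mb - s$motif_center) - abs(ma - s$motif_center))
    }, numeric(1)) |> mean()
  }
  expect_equal(mean_disp("C4a", "minus1"), 0, tolerance = 1.5)
  expect_equal(mean_disp("C1", "plus1"), 25, tolerance = 1.5)
  expect_equal(mean_disp("C1", "minus1"), 25, tolerance = 1.5)
  expect_equal(mean_disp("C4b", "minus1"), -25, tolerance = 1.5)
  expect_equal(mean_disp("C4b", "plus1"), 25, tolerance = 1.5)
})
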