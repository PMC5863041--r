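# chromfrag

Fragment-length footprinting of transcription factor–nucleosome promoter
architecture, for genomicists analysing paired-end MNase ChIP data.

In an MNase ChIP experiment each sequenced fragment is one protected DNA
molecule: its ends mark protection boundaries and its length reports
*what* was protecting it. Around a bound transcription factor the
fragment population mixes short factor-only footprints (~30 bp of
protected DNA plus digestion-dependent overhangs), ~150-bp weakly
protected fragments that vanish under heavy digestion, ~147-bp phased
nucleosomal fragments, and a diagnostic 160–220-bp class protected by
the factor **and** an adjacent nucleosome on the same molecule
("co-bound"). chromfrag turns those signals into estimates:

* **Footprint width** from stacked 5′/3′ fragment ends around oriented
  motifs: width = R − L + 1, where L and R are the modal 5′ and 3′ end
  offsets in the flanks.
* **V-plots** — 2-D histograms of fragment midpoint offset × fragment
  length around oriented anchors.
* **Promoter classification**: each site becomes a 21-bin
  fragment-length fraction vector (40–250 bp, 10-bp bins), clustered by
  K-means (K = 4) after a motif-presence filter and a bottom-15%
  read-depth filter; clusters are canonically ordered by long-fragment
  (≥160 bp) centroid mass.
* **Long-fragment asymmetry** relative to the TSS, score =
  (upstream − downstream)/total midpoints of co-bound-sized fragments
  covering the site — positive when the factor favours the −1
  nucleosome.
* **NET-seq directionality**: strand-split 3′-end coverage (each end
  extended 20 bp 5′-ward), an aborted-antisense-transcript score per
  site, and an exact 1-D 2-means split of the co-bound cluster into
  "locked" (4a) and "pushed" (4b) subclasses.
* **Nucleosome shifts** upon chromatin-remodeler depletion: occupancy =
  fragment midpoints extended ±25 bp; the −1/+1 shift is the argmax
  displacement in side windows, signed negative toward the site.

A synthetic chromatin simulator with per-fragment ground truth
(`sim_params()`, `build_site_panel()`, `simulate_chip_fragments()`,
`simulate_netseq_reads()`, `simulate_nucleosome_fragments()`) backs
every estimator with recovery tests. Standard formats are supported
throughout: BED6/bedGraph/narrowPeak/TSV, coordinate-sorted BAM
(via Rsamtools), FASTA consensus scanning with IUPAC codes (via
Biostrings). All coordinates are 0-based, half-open.

## Worked example

```r
library(chromfrag)
library(dplyr)

params  <- sim_params(n_sites_per_class = 20, fragments_per_site = 200,
                      seed = 7)
panel   <- build_site_panel(params)
frags   <- simulate_chip_fragments(panel, params)
anchors <- panel_anchors(panel, "tss")

cl <- cluster_profiles(length_profiles(anchors, frags), K = 4, seed = 1)
cl
#> <fragment-length K-means: K = 4, n = 100>
#> cluster sizes: 20, 20, 20, 40
#> centroid long-fraction (>=160 bp): 0.025, 0.091, 0.451, 0.673

long_fragment_asymmetry(frags, anchors) |>
  inner_join(tidy(cl), by = c(anchor_id = "peak_id")) |>
  group_by(cluster) |>
  summarise(mean_score = mean(score, na.rm = TRUE))
#> # A tibble: 4 × 2
#>   cluster mean_score
#>     <int>      <dbl>
#> 1       1    -0.0326
#> 2       2    -0.0890
#> 3       3    -0.0261
#> 4       4     0.790
```

The four canonical clusters recover the four simulated promoter classes
exactly (the two co-bound subclasses are indistinguishable by fragment
length and land together in cluster 4, hence its size 40). Cluster 4
carries 67% of its centroid mass in the ≥160-bp bins and a strongly
positive TSS-distal asymmetry (+0.79 ≈ 2×0.9 − 1 under the simulator's
0.9 distal-side placement), the co-bound signature; clusters 1–3 sit
near zero. `autoplot(vplot(frags, anchors))` draws the corresponding
V-plot, and `plot_cluster_centroids(cl)` the centroid length profiles.

The NET-seq and depletion arms continue from the same objects:
`aborted_transcript_score()` + `split_cluster4()` separate locked from
pushed sites, and `nucleosome_shift()` on
`nucleosome_profile()` pairs quantifies the −1/+1 response.
`run_analysis(run_config(simulation = params))` chains the whole
pipeline and writes TSV outputs plus a JSON summary.

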