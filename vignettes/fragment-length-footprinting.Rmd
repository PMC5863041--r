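---
title: "Fragment-length footprinting of promoter chromatin: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-length footprinting of promoter chromatin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromfrag)
library(dplyr)
```

## The measurement model

MNase digests protein-free DNA and stops at protein-bound or cross-linked
DNA, so in a paired-end MNase ChIP experiment each sequenced fragment is a
single protected DNA molecule, and its two ends mark protection
boundaries. Around a transcription-factor binding site the fragment
population decomposes into interpretable classes:

* **Factor-only fragments** span the ~30-bp protected region around the
  motif, plus a digestion-dependent overhang at each end. Stacking 5'
  and 3' fragment ends around the motif shows two sharp boundaries; the
  distance between the modal 5' and modal 3' end positions is the
  footprint width.
* **Co-bound fragments** (160-220 bp) are protected by the factor *and*
  one adjacent nucleosome on the same molecule. Their length sits near
  a protected region plus a nucleosome core (147 bp), and their midpoint
  falls between the motif and that nucleosome — in a V-plot they appear
  as a long-fragment cloud offset to one side.
* **Mid-length fragments** (~150 bp) centered on the motif are weakly
  protected DNA; their abundance collapses as digestion increases.
* **Nucleosomal fragments** (~147 bp) come from the phased -1/+1
  nucleosomes flanking the promoter nucleosome-depleted region (NDR).

Because the classes separate by fragment *length*, a binding site can be
summarized by a fragment-length histogram, and sites can be classified by
clustering those histograms. That is the core statistic of this package:
each site becomes a 21-bin fraction vector over lengths 40-250 bp (10-bp
bins, left-closed, top bin right-closed — the unique partition of that
range at 10-bp resolution), and sites are clustered by K-means with
K = 4. Canonical cluster labels are assigned by ascending centroid mass
in the bins at and above 160 bp ("long-fraction"), so cluster 1 is the
most factor-only-like and cluster 4 the most co-bound-like.

Two further measurements resolve cluster 4 into mechanistic subclasses:

* **Aborted antisense transcripts** (NET-seq): 3'-end reads on the
  antisense strand that terminate within 50 bp upstream of the motif.
  The per-site score is the count of such ends per 1000 in-window
  antisense reads — normalizing by antisense reads only makes the score
  invariant to the sense-transcription level, which varies for
  unrelated reasons. An exact 1-D two-group K-means (all contiguous
  splits of the sorted scores enumerated; deterministic) separates
  high-score ("4a", locked) from low-score ("4b", pushed) sites.
* **Remodeler-depletion response** (MNase-seq before/after): nucleosome
  occupancy is the coverage of fragment midpoints extended 25 bp each
  side (51 bases per fragment). The -1/+1 shift is the displacement of
  the occupancy argmax within side windows ([-250, -50] and [+50, +250]
  oriented; the argmax is robust at these profile sizes and ties break
  toward the anchor), signed so negative means motion toward the
  binding site. Locked sites show a -1 shift near zero; pushed sites
  show the -1 nucleosome sliding *away* when the remodeler is removed.

## Coordinate and counting conventions

All intervals are 0-based half-open (BED). A fragment's 3' end is its
last covered base (`end - 1`), so footprint width `R - L + 1` counts
inclusive bases and a fragment spanning exactly the protected region
`[c - 15, c + 15)` yields width 30. Fragment midpoints are
`floor((start + end - 1) / 2)`; even-length fragments take the left
central base. NET-seq 3' ends are extended 20 bp in the 5' direction
*inclusive of the 3' base*, i.e. 21 covered bases — chosen so the
coverage-mass conservation law (mass = 21 x reads) is exact. Boundary
rules follow strict readings throughout: peak centers match below 64 bp,
short fragments are below 80 bp, and peaks farther than 256 bp from the
nearest TSS are discarded (256 itself is retained). The bottom-fraction
read-depth filter removes `ceiling(f * n)` peaks — the only rounding
consistent with removing 140 of 929 at f = 0.15 — with ties broken by
input order for reproducibility.

## The synthetic chromatin simulator

The simulator is first-class, tested code: it generates ChIP fragments,
NET-seq 3' ends and nucleosome fragments from promoter architectures
with known per-fragment ground truth, so every estimator in the package
can be validated by recovery. Five site classes are emulated:

| class | mixture (tf_only / cobound / midfrag / nucleosomal at unit MNase) | distal-side probability |
|---|---|---|
| C1 | 0.75 / 0 / 0.10 / 0.15 | — |
| C2 | 0.40 / 0 / 0.45 / 0.15 | — |
| C3 | 0.45 / 0.35 / 0.05 / 0.15 | 0.5 |
| C4a, C4b | 0.25 / 0.55 / 0.05 / 0.15 | 0.9 |

C1 is factor-only; C2 is a digestion-sensitive continuum of factor-only
and mid-length protection; C3 is bimodal with symmetric nucleosome
choice; C4 is bimodal with a strong preference for the TSS-distal (-1)
nucleosome. C4a and C4b are identical in ChIP fragment composition by
construction — they differ only in NET-seq structure (C4a emits aborted
antisense 3' ends within 50 bp upstream of the motif; C4b initiates
antisense transcription from an upstream NDR ~350 bp out) and in their
depletion response (C4a's -1 dyad is locked; C4b's slides
away by the configured shift; C1/C2/C3 dyads move toward the motif,
the generic remodeler-loss response).

Key generative choices, and why:

* **Overhang model.** Factor-only fragments get an independent
  half-normal outward overhang per end,
  `round(|N(0, boundary_noise_sd / mnase_level)|)`. This produces sharp
  modal boundaries exactly at the protection edges while letting
  digestion level control boundary blur. The default
  `boundary_noise_sd = 12` bp (per end, at unit MNase) puts factor-only
  fragments at ~40-80 bp under light digestion, matching the short-
  fragment mode seen in real data; at heavy digestion (level 9-27) the
  overhang collapses and boundaries are near-exact.
* **MNase dependence of mid-length fragments.** Their mixture weight is
  divided by `mnase_level` — the simplest monotone rule implementing
  their near-disappearance at high digestion. The default level is 1
  (light digestion, the condition used for short-read peak work); the
  1/9/27 scale is the parameter's unit.
* **Co-bound lengths** are truncated-normal (190, 12) on [160, 220],
  sampled by inverse-CDF and rounded, so every emitted co-bound
  fragment respects the band by construction.
* **TSS geometry.** The TSS sits a fixed 120 bp downstream of the motif
  along the gene strand. Real promoters show a distance *preference*,
  not a constant; a fixed offset keeps oriented coordinates exact for
  recovery tests without changing any estimator.
* **Dyads.** -1/+1 dyads sit 130/140 bp from the motif center (the C4b
  -1 dyad abuts the protected region at `halfwidth + 74`), with N(0, 8)
  positional jitter and N(147, 5) fragment lengths.
* **Mid-length fragments** get N(0, 10) positional jitter: a perfectly
  centered even-length fragment always floors its midpoint one base
  upstream, which would bias the long-fragment asymmetry of symmetric
  classes; jitter restores the symmetry the class is meant to have.
* **NET-seq antisense fractions.** C1 uses exactly 1/2 (symmetric
  divergent initiation); C2/C3 use 0.35 (reduced divergence —
  unquantified in real data, chosen once as a plausible intermediate);
  C4a/C4b route 0.3 of reads to their class-specific antisense
  component.

What the simulator does *not* emulate — and therefore what passing
recovery tests do not show about real data: MNase sequence bias,
cross-linking-site preference, mappability structure, replication of a
real genome's composition, sequence-level reads (no FASTQ), overlapping
or weak binding sites, and biological variability in TSS distance and
nucleosome spacing. Recovery at ARI >= 0.9 on simulated panels
demonstrates the estimators are correct and well-conditioned, not that
real chromatin is this clean.

## Problem sizes and numerics

The default panel is 50 sites per class (250 sites) at 200 fragments per
site — enough that per-site 21-bin histograms are stable (about 170
in-range fragments each) while a full analysis runs in seconds. K-means
uses 25 seeded restarts (fixed-seed initialization; best total
within-cluster sum of squares), which at this separation always reaches
the same optimum; clustering is order-invariant after canonical
relabeling. Footprint estimation requires non-empty flank windows and
signals an error otherwise; length profiles with zero in-range fragments
are flagged and excluded from clustering; the cluster-4 split is refused
(flagged) when all scores are identical; flat occupancy windows yield
flagged `NA` shifts rather than arbitrary argmaxes.

## Worked example

```{r example}
params <- sim_params(n_sites_per_class = 20, fragments_per_site = 200,
                     seed = 7)
panel <- build_site_panel(params)
frags <- simulate_chip_fragments(panel, params)
anchors <- panel_anchors(panel, "tss")

profs <- length_profiles(anchors, frags)
cl <- cluster_profiles(profs, K = 4, seed = 1)
cl

asym <- long_fragment_asymmetry(frags, anchors) |>
  inner_join(tidy(cl), by = c(anchor_id = "peak_id")) |>
  group_by(cluster) |>
  summarise(mean_score = mean(score, na.rm = TRUE))
asym
```

Cluster 4 collects the co-bound sites: the highest long-fraction and a
strongly positive TSS-distal asymmetry, while clusters 1-3 sit near
zero or below.

```{r plots, fig.width = 6, fig.height = 4}
autoplot(vplot(frags, anchors, W = 300))
plot_cluster_centroids(cl)
```

## Known limitations

* Peak calling, alignment and motif discovery are out of scope: the
  package consumes called peaks, mapped fragments and known consensus
  patterns.
* The exact width of "the peak region" used for per-site histograms is
  a free parameter (default summit +/- 100 bp); published analyses do
  not pin it down, and cluster composition can move slightly with it.
* The canonical cluster ordering is by long-fraction; orderings between
  the middle clusters (continuum vs bimodal) are not guaranteed to
  match every published figure's numbering.
* Shift quantification uses the occupancy argmax; for very sparse
  profiles a cross-correlation estimator would be more stable, and the
  argmax is the deliberate, simpler default at the profile sizes used
  here.
* Background sampling ignores mappability (synthetic genomes are fully
  mappable).
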