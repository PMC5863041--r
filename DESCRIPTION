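Package: chromfrag
Title: Fragment-Length Footprinting of Transcription Factor-Nucleosome
    Promoter Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of paired-end MNase ChIP fragments around
    transcription factor binding sites: fragment-end stacking and footprint
    width estimation, V-plots (fragment midpoint by length), per-site
    fragment-length profiles with K-means classification of promoter
    chromatin configurations (factor-only versus factor-nucleosome
    co-bound), long-fragment asymmetry relative to the transcription start
    site, strand-split NET-seq coverage with aborted-transcript scoring,
    and quantification of nucleosome shifts upon remodeler depletion.
    Includes a synthetic chromatin simulator with per-fragment ground
    truth so every estimator can be validated against known promoter
    architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
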