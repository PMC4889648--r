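Package: splicescreen
Title: Sequencing-Based Reverse-Genetic Splicing Screens
Version: 0.1.0
Authors@R:
    person("Screen", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of pooled amplicon-sequencing splicing screens in
    arrayed deletion libraries. Converts dual-barcoded amplicon reads (or
    tabular spliced/unspliced counts) into per-strain splice-index
    measurements (unspliced/spliced read ratio), normalizes by 384-well
    plate medians, applies replicate-concordance and read-depth quality
    filters, fits a read-depth-aware empirical null (20 equal-size depth
    bins, natural cubic spline interpolation of the null mean and standard
    deviation), calls hits by Z-score with Benjamini-Hochberg correction,
    and tests cross-target hit overlap with Fisher's exact test. Includes
    a synthetic screen generator (beta-binomial counts, log-normal depths,
    barcoded FASTQ reads with ground truth) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    jsonlite,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
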