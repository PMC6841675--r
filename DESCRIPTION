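Package: samq
Title: Meristem Center Estimation, Radial Signal Quantification and
    Chromatin Interval Post-Processing for Plant Shoot Apical Meristems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification machinery for confocal and chromatin profiling
    studies of the Arabidopsis shoot apical meristem (SAM). Estimates the
    meristem center and central axis from segmented L1 nuclei by
    least-squares sphere fitting and a three-seed spherical Voronoi
    circumcenter construction; quantifies reporter signals radially from
    the center via rotated cross-section profiles, central-window
    statistics, threshold-distance ("auxin minimum size") metrics,
    stem-cell gating and min-max normalization, and Nadaraya-Watson kernel
    regression with bootstrap confidence bands; provides the classical
    group statistics (Student t, one-way ANOVA with Tukey HSD, Fisher
    exact, chi-square) used on the quantified outputs; and post-processes
    ChIP-derived genomic intervals (posterior filtering, reduction,
    opposite-direction conflict removal, promoter-window annotation, Venn
    overlaps, TSS metaprofiles, Fisher enrichment against a background
    gene universe). Seeded synthetic-data generators produce meristem
    point clouds, surface intensity grids and toy genomic-interval worlds
    with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
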