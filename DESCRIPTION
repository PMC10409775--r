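Package: dropsort
Title: Poisson Encapsulation Statistics, Droplet Sorting Simulation and
    Barcode-Level QC for Droplet Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistics of droplet microfluidic single-cell
    RNA-seq with fluorescence-activated droplet sorting (FADS). Provides a
    closed-form Poisson model of cell and bead co-encapsulation with a
    live/dead viability split, a seeded Monte-Carlo simulator of droplet
    generation, per-droplet fluorescence and threshold sorting, a synthetic
    droplet count-matrix generator with planted cell types, damaged cells,
    empty droplets, ambient RNA, spliced/unspliced layers and optional
    two-species barnyard structure, barcode-level quality control (ranked
    barcode knee detection, fraction of reads in cells, hypergeometric
    downsampling, nuclear-fraction classification, mitochondrial content,
    barnyard doublet estimation), and cluster label transfer by maximum
    Pearson correlation of mean expression profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
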