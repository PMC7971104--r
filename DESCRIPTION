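Package: umicna
Title: Copy-Number Alteration Calling from UMI Depth on Targeted Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects somatic copy-number alterations in UMI-tagged targeted
    gene-panel sequencing by counting unique molecular identifiers (UMIs) per
    targeted region instead of reads. Builds a filtered pseudo-reference from
    control samples (geometric mean with RMSD-based outlier exclusion),
    computes centered log2 ratios for tumor samples (Gaussian-mixture diploid
    centering), segments each gene with weighted circular binary segmentation,
    calls gain and loss segments with FDR-corrected one-sample t-tests, and
    estimates tumor content from significant segment means. Includes a
    ground-truthed synthetic-data generator for panels, control cohorts,
    spiked CNV events at programmable tumor fraction, and micro-BAM fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    mclust,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
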