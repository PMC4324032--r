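Package: zurchip
Title: Peak Calling and Operator-Box Analysis for Bacterial ChIP-on-Chip
    Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide mapping of transcription-factor binding sites from
    two-color ChIP-on-chip tiling arrays on circular bacterial chromosomes.
    Implements loess dye-bias correction of log2 IP/WCE ratios on the MA
    plot, two-round sliding-window smoothing, window-extremum peak detection
    scored with the ChIPScore enrichment statistic, replicate reconciliation,
    position-weight-matrix scanning with exact tail p-values computed by
    dynamic programming, and classification of binding sites relative to
    translational start sites. A fully specified synthetic tiling-array
    simulator with planted operator boxes provides ground truth for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
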