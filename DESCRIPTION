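Package: tfrewire
Title: Condition-Specific Transcription Factor Target Groups and Their
    Transcriptional Impact
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of transcription-factor binding across two
    cellular conditions. Categorises peak sets into condition-specific and
    shared groups, assigns peaks to nearest-TSS genes to derive gene-level
    target groups, quantifies overlap of peak sets with enhancer classes and
    co-factor binding through hypergeometric tests against an explicit
    background universe of regions, and scores the transcriptional impact of
    target groups with a size-matched bootstrap null on mean log2 fold
    change. Includes spike-in-normalised CUT&RUN quantification, DEG
    filtering, rank-based group comparisons, and a synthetic-data module
    that plants known peak composition and expression effects so every
    stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
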