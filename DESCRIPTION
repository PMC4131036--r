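Package: AFSeq
Title: Species Quantification in Mixed DNA Samples by Reference Read Counting
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the species composition of a mixed total-DNA sample by
    mapping deep-sequencing reads against a panel of reference genomes and
    counting them per genome: uniquely mapping reads are counted directly,
    multi-mapped reads are redistributed in proportion to the unique-read
    counts of their candidate genomes, and counts are corrected by a per-genome
    quality factor f = (n + c)/c that compensates for ambiguous (N) positions
    in draft references. Residual unmapped reads are taxonomically classified
    from tabular similarity-search output by a filtered lowest-common-ancestor
    procedure, and strongly supported unexpected taxa can be promoted into the
    mapping panel for a second, more accurate quantification pass. Ships a
    deterministic simulator for reference panels with controlled divergence and
    tagged error-bearing reads, used to validate the method end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    Rsamtools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
biocViews: Metagenomics, Sequencing, Alignment, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
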