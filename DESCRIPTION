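Package: binmeth
Title: Bin-Based Differential Methylation Analysis for Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing plant whole-genome bisulfite sequencing
    (WGBS) methylomes at fixed 100-bp resolution: reading per-cytosine
    bismark-style reports, pooling replicates, computing context-stratified
    weighted methylation levels in genomic bins, calling differentially
    methylated regions (DMRs) by screening bins on differentially
    methylated cytosine counts and level differences and merging nearby
    candidate bins, detecting ectopic CHG methylation gained at loci
    unmethylated in a control, annotating DMRs against gene and
    transposable-element features, intersecting DMR-proximal genes with
    differentially expressed gene lists, computing gene-body methylation
    metaplots and chromosome-scale hypomethylation ratio tracks,
    quantifying transgenerational restoration of methylation at DMRs and
    epiallele segregation between sibling lines, and an exact multi-set
    intersection test. Includes a WGBS read-count simulator with planted
    differentially methylated regions for end-to-end validation against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
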