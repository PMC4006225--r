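Package: targetCMA
Title: Software-Targeted Prenatal Chromosomal Microarray Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for software-targeted prenatal chromosomal microarray
    (array-CGH) analysis. Segments paired two-channel 60K oligonucleotide
    array data into copy-number variant (CNV) calls with a quality-weighted
    interval z-score statistic, assigns each call to the carrier sample
    using run-mate reference arrays, classifies calls against a configurable
    3 Mb backbone plus targeted deletion/duplication syndrome regions, and
    produces masked prenatal reports as well as full-resolution "unmasking"
    reanalyses, resolution sweeps and size-threshold summaries. Includes a
    paired-hybridization array simulator with known truth CNVs and
    machine-readable fixtures of a published prenatal cohort for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    yaml,
    jsonlite,
    grDevices,
    graphics,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: CopyNumberVariation, aCGH, Microarray, Software
RoxygenNote: 7.3.3
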