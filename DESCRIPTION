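Package: rrhp
Title: Reduced Representation Hydroxymethylation Profiling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for reduced representation hydroxymethylation
    profiling (RRHP) of 5-hydroxymethylcytosine at MspI (CCGG) junctions:
    in-silico restriction digestion and junction cataloguing, strand-aware
    counting of junction reads from alignments, a two-step count-abundance
    filter, precision-weighted moderated differential hydroxymethylation
    testing with Benjamini-Hochberg false discovery rate control,
    multidimensional scaling diagnostics, genomic feature annotation of
    differentially hydroxymethylated cytosines, and a chemistry-faithful
    synthetic read generator so that every stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
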