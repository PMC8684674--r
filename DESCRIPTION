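Package: insertscout
Title: Genome-Wide Insertion-Site Discovery from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects the genomic landing sites of known inserted elements
    (transposons such as Tnt1 or Ds, or T-DNA) from Nanopore-style long
    reads. Reads carrying the target element are identified with a built-in
    seed-and-extend local aligner (or external BLASTN tabular output), the
    flanking sequences on either side of the element are extracted with
    their junction orientation, mapped back to the reference genome, and
    the resulting breakpoints are clustered into supported insertion sites
    with nearby-gene annotation. Site read counts are scored against a
    zero-inflated Poisson background fitted to windowed genome-wide counts.
    Includes a synthetic-data generator (mutant genomes with planted
    insertions and noisy long reads), a combinatorial barcode-pooling
    designer/decoder for multiplexed mutant panels, and a command-line
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    readr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
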