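Package: apisrna
Title: Stranded RNA-Seq Duplex Screening, Composition Summaries, and
    Multiphasic Binding-Curve Analysis for Royal Jelly RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing extracellular RNA of honeybee royal jelly
    and its protein partners. Implements a strand-specific screen for
    putative double-stranded RNA from read overlaps (minimum-overlap /
    maximum-overhang rule) with per-gene quantification and median-of-ratios
    normalization; species and RNA-biotype composition summaries with
    mean-ratio library-size factors, Welch tests and strand-specific
    coverage; gene-length-bias-aware GO overrepresentation using the
    Wallenius noncentral hypergeometric distribution; multiphasic
    ligand-depletion binding-isotherm simulation and fitting with BIC phase
    selection; and a synthetic-data generator producing toy genomes, stranded
    paired-end alignments with planted duplexes, GO annotations and noisy
    titrations so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    minpack.lm,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
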