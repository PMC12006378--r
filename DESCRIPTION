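Package: mitorecomb
Title: Structural Analysis of Multichromosomal Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of multichromosomal plant
    mitochondrial genomes assembled as circular chromosomes. Discovers
    dispersed repeat pairs and simple sequence repeats, builds the four
    flank-switched reference configurations around a repeat, classifies
    long reads as spanning support for each configuration and computes the
    repeat-mediated recombination frequency, enumerates the circular
    genome configurations reachable by repeat-mediated homologous
    recombination (fusion, fission and inversion of segment cycles),
    detects plastid-derived insertions (MTPTs), calls C-to-U RNA editing
    sites from strand-resolved pileups with codon-level effect annotation,
    and derives interspecific intron markers from aligned orthologous
    introns. A synthetic-data module generates every input with known
    ground truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils
Suggests:
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
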