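Package: satellitome
Title: Satellite DNA Discovery, Cataloguing and W-Chromosome Enrichment
    Analysis from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for characterizing the satellite DNA
    complement (satellitome) of a genome from unassembled short reads and
    for detecting sex-chromosome-linked repeat accumulation in
    female-heterogametic (ZZ/ZW) species. Implements an iterative
    satellite-mining loop (read sampling, k-mer clustering, tandem-period
    detection, masking), a three-level variant/family/superfamily catalog
    built on circular strand-aware sequence identity, per-library
    abundance and Kimura 2-parameter divergence estimation with repeat
    landscapes, subtractive female-minus-male landscapes and F/M ratio
    ranking of W-chromosome candidates, monomer haplotype minimum
    spanning trees, and two non-invasive sexing calculators (quick-FISH
    spot counting and qPCR delta-Ct relative quantification). A synthetic
    paired ZW/ZZ genome and read simulator with a machine-readable truth
    table makes the whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
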