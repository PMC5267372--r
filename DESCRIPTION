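Package: gcassembler
Title: Protein-Alignment-Guided Gene-Centric Assembly of Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Assembles sequencing reads binned to a single orthologous gene
    family into contigs, using an overlap-layout-consensus scheme in which
    read overlaps are induced by the reads' protein alignments to a common
    reference: each read is reduced to its aligned core (the segment covered
    by its highest-scoring local protein alignment, oriented by frame),
    cores become nodes of a directed overlap graph whose edges are
    perfect-identity gap-free DNA suffix-prefix overlaps, contigs are
    extracted as maximum-weight paths after cycle breaking, and a second
    contig graph removes contained contigs and merges overlapping ones.
    Includes a self-contained simulator that generates gene families,
    tiled reads and exact protein-alignment records for testing, and a
    command-line driver script.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
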