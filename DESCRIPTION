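Package: sporomir
Title: Conserved miRNA Identification and Degradome Analysis for Genome-Poor Plant Lineages
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A small-RNA analysis toolkit for plant lineages with few or no
    sequenced genomes, such as lycophytes and ferns. Identifies conserved
    microRNA candidates from small RNA-seq reads by homology to a reference
    catalog of annotated plant mature miRNAs, clusters isomiRs by their 5'
    1-16 nucleotides, normalizes 3' uridine tails, validates candidates
    against genomic hairpin structures, calls cleavage peaks in
    degradome/PARE libraries with a four-rule local algorithm, links peaks
    to candidate miRNAs through plant-style target scoring with G:U wobble
    penalties, and computes cross-species conservation statistics (size
    distributions, 5' nucleotide composition, per-family nucleotide
    variation, and expression-based conservation classes). A seeded
    synthetic-data generator produces ground-truthed read libraries,
    planted hairpins, and degradome tags so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
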