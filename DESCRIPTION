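Package: polatyper
Title: Marker-Gene Typing and Replisome Profiling of Virioplankton Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for typing phage DNA polymerase I (PolA) sequences from
    assembled viral metagenome contigs. Peptides are screened against a marker
    panel, anchored to a reference PolA by ends-free global alignment so the
    residue at the (E. coli-numbered) 762 position can be read off, clustered
    at 75% amino-acid identity by furthest-neighbour linkage, and profiled for
    co-located replication genes (helicase families, ribonucleotide-reductase
    classes, primase, MazG). Distance-based trees over reference-anchored
    windows, concatenated PolA+RNR clade assignment, per-clade core gene
    clusters, a rule-based "field guide" lifestyle classifier, and a seeded
    synthetic community generator with a ground-truth table round out an
    end-to-end, fully offline analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
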