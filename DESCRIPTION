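Package: genopanel
Title: Comparative Genome-Panel Analysis, Assembly QC and 16S Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for rule-driven functional gene inventories (two-component
    systems, transcription factors, transporters, defense genes), structural
    and chromosomal-organization classification of two-component systems,
    cross-genome standardized count statistics including a combined z-score
    ranking, COG-profile correlation clustering, assembly reconciliation and
    coverage-based copy-number QC, repeat catalogues (global, inverted,
    tandem), and neighbor-joining 16S trees with bootstrap support. Seeded
    synthetic-data generators emulate annotated genomes, genome panels,
    fragmented assemblies and alignments evolved on known trees so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
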