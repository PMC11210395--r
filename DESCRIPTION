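Package: phagecode
Title: Genetic-Code-Aware Gene Calling and Stop-Codon Reassignment
    Detection for Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts stop-codon reassignment in bacteriophage genomes
    before annotation and quantifies its impact on annotation quality.
    Provides candidate genetic codes (NCBI translation tables 11, 4 and
    15), a six-frame ORF engine, a self-training hexamer gene caller with
    dynamic-programming gene selection, a coding-density based selector
    that chooses the genetic code of a genome, a heuristic cloverleaf
    detector for amber/opal/ochre suppressor tRNAs, per-genome annotation
    metrics with paired-test comparisons, and a synthetic phage-genome
    generator with known ground truth for end-to-end validation. Includes
    a command-line interface for simulation, gene calling, code selection,
    tRNA scanning and annotation comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
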