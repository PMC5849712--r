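Package: ecasplice
Title: Alternative Splicing Event Calling and Cross-Species Conservation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and filters splice junctions from spliced RNA-seq
    alignments, calls the five principal plant alternative-splicing event
    types (exon skipping, intron retention, alternative donor, alternative
    acceptor and alternative position), matches event signatures across
    several species mapped to one shared reference to identify
    evolutionarily conserved alternative splicing (ECAS) events, and
    evaluates the coding consequences of single-event genes (premature
    termination codons and frameshifts).  Includes the comparative
    statistics used in such surveys (likelihood-ratio G-test, exact
    Wilcoxon rank-sum) and a seeded simulator that generates toy genomes,
    annotations and multi-species spliced alignments with planted, labeled
    events so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
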