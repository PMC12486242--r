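Package: muflap
Title: Prophage Activity Analysis from Mu-Like Packaging Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying temperate-phage activity from sequencing
    data of Mu-like (transposable) and integrase-encoding prophages. Extracts
    the 20-nt host-derived 5' flaps that headful packaging places at both ends
    of Mu-like virion genomes, classifies them as original (native locus) or
    new (replicative-transposition) flaps, and estimates the average burst
    size as (original + new) / original flaps. Scans host chromosomes for the
    degenerate 5-bp Mu target consensus NYSRN, computes per-gene transposition
    target preference (TTP) scores, ranks genes into bins, and calls
    transposition hot and cold spots by hypergeometric category enrichment.
    Detects spontaneous prophage induction in cellular DNA via new flaps
    (Mu-type) or attP-spanning junction k-mers (integrase-type), and locates
    cos-type genome termini from read-start pile-ups. Computes RPKM-based
    prophage and host abundances, virus-to-host ratios, and log-log abundance
    slopes for Piggyback-the-Winner inference. A fully seeded synthetic-data
    generator produces ground-truthed lysogens, transposition events, packaged
    particles, reads and abundance tables so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
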