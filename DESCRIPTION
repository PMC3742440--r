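Package: chipprox
Title: Peak-to-TSS Proximity, Enrichment and Consensus Motif Statistics for ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of ChIP-seq peak calls aimed at linking a
    transcription factor's binding sites to cell-type-specific gene programs.
    Filters treatment peaks against a control condition, assigns peaks to
    strand-aware windows around transcription start sites, compares observed
    peak counts per gene list with a uniform-genome expectation (fold
    enrichment and chi-squared tests), builds TSS-relative incidence
    histograms and multi-factor peak overlap summaries, and provides IUPAC
    consensus motif scanning with central-enrichment, spaced-pair and
    discriminative k-mer discovery statistics. A synthetic-data module
    generates genomes, gene lists, peak sets with planted TSS-proximal
    enrichment, and sequence sets with planted motifs, recording ground truth
    so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
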