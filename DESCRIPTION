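Package: gfuse
Title: Cohort-Based Fusion Transcript Detection for Degraded FFPE RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fusion transcripts in single-end 50 bp directional
    RNA-Seq reads from degraded (formalin-fixed paraffin-embedded) RNA.
    Implements split-read discovery with a local-realignment retest filter,
    annotation-based fusion candidacy rules, five-template-set construction
    with duplicate and homology filters, template remapping for junction
    support, library-size normalization with exon/intron Interrupt Ratio
    expression profiling, and cohort-based three-tier evidence
    classification with reading-frame prediction. Ships a synthetic FFPE
    cohort simulator (toy genomes, refGene annotation, FASTQ read sets with
    implanted fusions and a machine-readable truth set) so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
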