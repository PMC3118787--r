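Package: ESTpipe
Title: EST Clustering, Full-Length Transcript, Digital Expression, SSR and
    SNP Analysis for Sanger cDNA Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of expressed sequence tags
    (ESTs) generated from full-length enriched and standard cDNA libraries.
    Provides quality trimming and contaminant screening of clone-end reads,
    a greedy overlap clusterer that groups reads into unigenes with
    consensus sequences, identification of full-length transcripts from
    5'/3' clone-end pairing with CDS/UTR annotation and codon-usage
    statistics, digital differential expression from per-tissue EST counts
    using the Stekel log-likelihood R statistic with Benjamini-Hochberg
    correction, a perfect-microsatellite (SSR) scanner with canonical motif
    grouping, and cross-cultivar SNP discovery from unigene alignments with
    coverage and allele-disjointness filters. A seed-driven synthetic EST
    study generator with machine-readable truth tables supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pheatmap
biocViews: Sequencing, Transcriptomics, Clustering, SNP, GeneExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
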