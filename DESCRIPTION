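Package: trconflict
Title: Transcription-Replication Conflict Analysis from OK-seq, DRIP-seq
    and Double-Strand Break Mapping Data
Version: 0.1.0
Authors@R: person("TRC", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for studying conflicts between
    transcription and DNA replication in mammalian genomes.  Derives
    replication fork directionality (RFD) from stranded Okazaki-fragment
    counts (OK-seq), detects replication initiation zones, classifies
    head-on versus codirectional replication at gene boundaries, calls
    enrichment peaks from immunoprecipitation tracks (DRIP-seq R-loops,
    phospho-RPA, gamma-H2AX) with a Poisson local-background model and
    Benjamini-Hochberg q-values, builds expression-stratified metagene
    profiles and TTS heatmaps, quantifies break signal (i-BLESS) at
    transcription termination sites, and classifies DSB-positive genes by
    hierarchical clustering.  Ships a seeded synthetic multi-omics
    generator with planted ground truth so the full pipeline is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
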