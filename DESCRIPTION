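Package: topomut
Title: Topography of Mutational Signatures Along the Genome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Compares somatic mutations attributed to mutational signatures
    against context-preserving simulated mutations with respect to
    transcription and replication strand, replication timing, and occupancy
    of topographical features such as nucleosomes, CTCF binding sites and
    histone marks. Provides SBS-96/DBS-78/ID-83 channel classification, a
    trinucleotide-context-preserving background simulator, strand
    annotation from gene models and Repli-seq profiles, odds-ratio
    asymmetry tests against simulated nulls, replication-timing decile
    densities, strand-coordinated mutagenesis detection, occupancy and
    abundance analysis around mutations, and a seeded synthetic-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
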