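Package: umidemux
Title: Demultiplexing and UMI-Aware Duplicate Marking for Multiplexed
    Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to process multiplexed high-throughput sequencing
    libraries that carry sample barcodes and unique molecular identifiers
    (UMIs) in flexible configurations: inline barcodes at read starts,
    separate Illumina index files, per-end or redundant paired-end
    barcodes, and composite barcodes mixing random UMI bases with the
    sample index. Provides demultiplexing of FASTQ files with
    mismatch-tolerant barcode assignment, extraction of UMIs into read
    headers, UMI-aware marking or removal of PCR duplicates in
    coordinate-sorted SAM/BAM alignments, and a seeded synthetic-library
    generator with full ground truth for validating every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    Rsamtools,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
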