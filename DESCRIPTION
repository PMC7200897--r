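Package: exoPipe
Title: Quality-Controlled Analysis of ChIP-exo Binding Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of ChIP-exo experiments, from aligned
    paired-end reads to quality-controlled transcription-factor binding
    profiles, SNR-filtered peaks and gene-target tables. Implements
    paired-end PCR-duplicate removal keyed on both mate positions, a
    protein-size-based footprint/trim-length estimate, strand-specific
    coverage with a both-strand-overlap filter, background normalization
    and replicate merging, replicate correlation and TSS meta-profile
    quality control, GEM event post-processing with peak-to-gene
    assignment, and a synthetic read simulator with a signal/noise
    mixing design for validating the whole pipeline without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
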