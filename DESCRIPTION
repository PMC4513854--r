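Package: ChIPcooc
Title: Two-Factor Co-Occupancy Analysis for ChIP-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A self-contained, testable implementation of a ChIP-seq
    co-occupancy workflow for two transcription factors: aligned-tag
    processing (deduplication, input downsampling, 3'-extension to
    fragments, 32-nt binned signal maps), a transparent local-Poisson
    enrichment peak caller with swap-based empirical FDR, TSS-relative
    and nine-category gene-feature annotation against a resampled
    input-tag control, IUPAC consensus / PWM / dimeric inverted-repeat
    motif scanning with exact dynamic-programming p-values, four-way
    motif classification of peaks, two-factor tag-count scatter and
    per-class regression, and the arithmetic of ChIP-qPCR percent-input
    and 2^(-ddCt) quantification. Includes a synthetic-genome simulator
    with planted binding sites and a truth table for end-to-end
    benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'ChIPcooc-package.R'
    'formats.R'
    'annotation.R'
    'signal-map.R'
    'cooccupancy.R'
    'motifs.R'
    'peak-calling.R'
    'simulate.R'
    'pipeline.R'
    'qpcr.R'
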