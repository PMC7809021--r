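Package: tadlink
Title: Linking Differential Chromatin Accessibility to Gene Expression
    Through Topologically Associating Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative regulatory-genomics pipeline that links
    differentially accessible chromatin regions (DARs, from ATAC-seq style
    read-start tracks) to differentially expressed genes through the 3D
    framework of topologically associating domains (TADs), and detects
    transcription-factor motif and binding-site redistribution between a
    parental and a transformed cell state. Includes a simplified
    local-Poisson peak caller, comparative DAR calling, strand-aware
    peak-to-feature annotation, smallest-TAD gene assignment, a permutation
    test for the genomic segregation of up- and down-regulated domains,
    PWM motif scanning with exact threshold calibration, ChIP-peak overlap
    statistics, 4C-seq sliding-window profiling, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
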