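Package: m6Astoich
Title: Quantitative RNA Modification Stoichiometry from Per-Read Calls
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether a perturbation changes RNA
    modification stoichiometry. Builds confidence-filtered per-site m6A
    pileups from per-read modification probabilities (bedMethyl-compatible),
    calibrates coverage thresholds from replicate-to-replicate concordance,
    derives an empirical null band from Bland-Altman limits of agreement and
    classifies differential sites against it, quantifies m6Am stoichiometry
    at snRNA transcription-start nucleotides from conversion-based
    (CROWN-seq style) read counts, counts CRISPR/RNAi dependency from
    DepMap-layout matrices, and simulates all required inputs so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epitranscriptomics, Sequencing, RNASeq, Coverage,
    DifferentialMethylation
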