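Package: repeatsizer
Title: Densitometry, Ladder Calibration and Trinucleotide-Repeat Sizing for
    Dual-Channel Microfluidic Electrophoresis Micrographs
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis engine for dual-channel microfluidic DNA
    electrophoresis: extracts background-corrected intensity profiles from
    16-bit fluorescence micrographs, deconvolves them into Gaussian bands,
    calibrates a position-to-size mapping from a reference DNA ladder,
    sizes and quantifies sample bands, converts amplicon lengths to CAG/CTG
    trinucleotide-repeat counts for the HTT and DMPK loci, and scores
    allele-length heterogeneity. A synthetic micrograph simulator with
    ground-truth bookkeeping makes every stage testable without laboratory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
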