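Package: msptyper
Title: Custom MALDI-TOF MS Reference Libraries for Bacterial Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open workflow for building custom MALDI-TOF mass-spectrometry
    reference databases of bacterial main spectral profiles (MSPs) and using
    them for species-level identification. Provides spectral preprocessing
    (SNIP baseline subtraction, Savitzky-Golay smoothing, quality control,
    peak picking), replicate-consensus MSP construction with frequency
    filtering and self-score validation, log-score classification on the
    0-3 scale with a replicate-consensus identification rubric, composite
    correlation index (CCI) matrices for strain-level comparison, spectral
    dendrograms, a 16S rRNA marker-gene layer (pairwise identity, taxonomy
    thresholds, OTU clustering, neighbor-joining trees) and a concordance
    tabulation between the two identification methods, including handling of
    taxonomic groups whose 16S rRNA sequences are nearly identical. A
    synthetic-data module generates ground-truthed spectra and sequence sets
    so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    signal,
    ape,
    Biostrings,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
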