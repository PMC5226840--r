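Package: rhythmcomp
Title: Rhythm Detection and Comparative Analysis of Diurnal Transcriptome Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rhythmic transcripts in diurnal/circadian expression time
    courses with two complementary algorithms (model-based waveform pattern
    matching with a permutation-calibrated correlation cutoff, and a
    nonparametric Kendall-concordance periodicity test with exact null
    p-values), performs circular (mod-24 h) phase statistics including
    dawn-corrected averaging and phase-pair adjustment, collapses
    transcript-level calls to genes and maps them to orthologs via supplied
    tables, and compares rhythmic gene sets across datasets by Venn
    partitioning, Tanimoto-Jaccard similarity ranking, and tissue-presence
    binning. Includes a synthetic time-course generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
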