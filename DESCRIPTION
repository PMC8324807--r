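Package: pamscreen
Title: Survival-Screen Analysis of PAM Libraries for Bacterial Base Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative workflow for base-editing-coupled survival screens of
    randomized protospacer-adjacent-motif (PAM) libraries. Simulates
    counterselection population dynamics of edited versus unedited genotypes,
    generates synthetic amplicon FASTQ read sets with ground truth, classifies
    reads into per-PAM target-codon editing outcomes by anchor matching,
    computes per-PAM base-editing efficiencies and enrichment factors, and
    renders PAM-pattern summaries as max-normalized heatmaps, information
    content sequence logos and PAM wheels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
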