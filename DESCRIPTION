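Package: luredisplay
Title: Scoring and Population Statistics for Polymorphic Mantle-Lure Displays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the aggressive-mimicry mantle-lure displays of
    polymorphic freshwater mussels from frame-annotated video scoring. Reads
    per-flap movement-event tables, classifies left-right synchronization with a
    frame tolerance, computes interval/duration/synchrony summaries and gait
    diagrams, compares lure groups with rank tests and a bootstrap-fed
    random-intercept mixed model, and tests morph-frequency stability and
    Mendelian segregation of brood phenotypes with exact tests. A synthetic-data
    generator produces coupled bilateral event trains and single-locus broods so
    the whole pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
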