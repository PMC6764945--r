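Package: mirarmkit
Title: miRNA Arm-Imbalance, Pull-Down Enrichment and TDMD Site Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying microRNA arm imbalance and target-directed
    miRNA degradation (TDMD) in cancer cohorts. Implements qPCR relative
    (2^-ddCt) and absolute (standard-curve) quantification, per-patient
    risk factors and linear risk scores with Kaplan-Meier stratification,
    paired tumor/normal arm-trend classification, biotinylated pull-down
    enrichment-ratio statistics with CDF-shift (Kolmogorov-Smirnov)
    testing, miRNA:target duplex alignment and TDMD-competent site
    classification with bulged sponge design, and isomiR trimming/tailing
    profiling of small-RNA reads. A seeded synthetic-data module generates
    every input with planted ground truth for recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
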