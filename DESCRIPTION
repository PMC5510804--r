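Package: stabilome
Title: Genome-Wide mRNA Stability Analysis from Actinomycin-D Chase RNA-Seq
Version: 0.1.0
Authors@R:
    person("Stabilome", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling the mRNA stabilome from transcription-shutoff
    (actinomycin D chase) RNA-seq count data. Computes per-gene stability
    ratios (chase over no-chase expression), classifies transcripts into
    stability classes, tests time-dependent differential mRNA stabilization
    with a dependent-ratio negative-binomial GLM and likelihood-ratio test,
    ranks genes by stabilization degree, relates expression level and
    induction kinetics to stability, and clusters induction time courses.
    Includes a negative-binomial count simulator with known per-gene decay
    rates and induction kinetics for end-to-end validation, plus a
    command-line interface covering the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    IRanges
Config/testthat/edition: 3
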