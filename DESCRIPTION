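Package: epimark
Title: Histone-Mark ChIP-seq Occupancy and Developmental Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for histone-modification ChIP-seq time courses.
    Converts uniquely mapped reads to fragment midpoints, builds depth-normalized
    100-bp coverage tracks and TSS metaprofiles with LOWESS smoothing, detects
    enriched regions with a Poisson sliding-window model filtered against a mock
    (anti-GFP) control, computes length- and depth-normalized interval occupancies
    (TSS +/- 2.5 kb, promoter, gene body), classifies genes into developmental
    epigenetic signature classes (unmarked, rod-specific de novo H3K4me2,
    non-rod retinal, ubiquitous), clusters stage-by-mark occupancy profiles, and
    runs promoter-vs-gene-body and wild-type-vs-mutant comparisons. Includes a
    seeded synthetic-data generator that plants known signature classes so the
    whole pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
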