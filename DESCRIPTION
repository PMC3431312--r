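Package: ChaseDecay
Title: mRNA Half-Life Estimation and Differential Stability from
    Transcription-Shutoff Chase Time Courses
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates transcriptome-wide mRNA half-lives from actinomycin-D
    transcription-shutoff (chase) time courses by nonlinear least-squares
    fitting of first-order decay, applies fit-quality and confidence-interval
    reliability filtering, and tests for differential mRNA stability between
    two conditions. Includes estimation of steady-state abundance changes
    from the time-zero arrays, analysis of decay-transcription coupling
    (transcriptional buffering) with a nascent pre-mRNA consistency check,
    qPCR-based half-life validation via delta-delta-Ct quantification, and a
    fully parameterised synthetic-data generator emulating the chase design
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
biocViews: GeneExpression, TimeCourse, Transcription, Microarray,
    DifferentialExpression, Software
RoxygenNote: 7.3.3
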