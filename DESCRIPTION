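Package: gonogophys
Title: Spike-Train and Behavioral Analysis for Go/No-Go Visual Task
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for head-fixed Go/No-Go visual discrimination
    experiments with extracellular recordings, optogenetic manipulation and
    fiber photometry. Computes behavioral discriminability (d-prime), lick
    latencies, waiting-period firing-rate indices (selectivity, outcome
    modulation, response index, laser rate change), normalized population
    PSTHs, orientation tuning curves with a circular-moment orientation
    selectivity index, broad/narrow spike-waveform classification, optogenetic
    phototagging via a stimulus-associated spike-latency test, and
    event-aligned fluorescence (dF/F) quantification. Includes a seeded
    synthetic-session generator reproducing the statistical structure of such
    recordings so every stage of the pipeline is testable without recorded
    data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
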