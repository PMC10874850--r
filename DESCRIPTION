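Package: meaphys
Title: Electrophysiological Phenotyping of Spike-Sorted HD-MEA Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workbench for extracting single-cell and network-level features
    from spike-sorted high-density microelectrode array (HD-MEA) recordings of
    neuronal cultures, and using them for machine-learning-assisted phenotype
    classification, age regression, developmental trajectory statistics and
    unit-level cell typing under pharmacological perturbation. Includes a
    seeded synthetic-culture generator (gamma-renewal firing modulated by
    network-burst envelopes, parametric extracellular waveform templates) so
    that every downstream stage can be exercised with known ground truth,
    readers for phy/Kilosort-style spike-sorter output and a portable JSON/CSV
    exchange bundle, unit quality control, waveform and spike-train metrics, a
    22-metric time-series feature set on binned activity, adaptive network
    burst detection, spike-time-tiling-coefficient and cross-correlogram
    functional connectivity graphs, random-forest phenotyping with batchwise
    z-scoring and permutation importance, linear mixed-effects trajectory
    tests, and Louvain unit clustering with perturbation-response mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    igraph,
    randomForest,
    lme4,
    lmerTest,
    uwot,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
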