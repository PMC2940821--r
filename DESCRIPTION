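Package: PerturbLink
Title: Boolean Inference and Linear Prediction of Signaling Networks from
    Perturbation Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers cause-effect signaling networks from
    single-stimulus/single-inhibitor phosphoprotein perturbation data and
    predicts protein activity under combinatorial (multi-stimulus,
    multi-inhibitor) treatments. Per-protein Boolean tables classify each
    stimulus and inhibitor action as significant or not against a
    measurement-error model (additive technical noise plus proportional
    biological noise) scaled by a significance multiplier k; the tables are
    translated into a directed network over stimulus, inhibited-protein and
    measured-protein nodes, redundant direct links are pruned, and links are
    ranked by the largest k at which they survive. Combinatorial conditions
    are predicted by linear superposition of single-perturbation training
    data routed through the reconstructed network. Includes DREAM-style
    scoring (normalized squared error, resampling-null p-values, Prediction
    and edge-penalized Overall Scores), a MIDAS-dialect CSV reader/writer,
    SIF export, a seeded synthetic-data generator for end-to-end validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
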