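Package: sccapacity
Title: Channel-Capacity Metrics for Single-Cell Measurement Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies the quality of single-cell gene-expression
    measurements in bits. Per-cell measurements taken across a ladder of
    environmental stimulus levels are discretized into empirical transition
    matrices, and the channel capacity between stimulus and measured output
    is computed with the Blahut-Arimoto algorithm. Includes the
    Freedman-Diaconis-seeded bin-doubling procedure for choosing the number
    of histogram bins, replicate aggregation (mean and sample standard
    deviation) with measurand-matched method comparison, and a synthetic
    two-channel (biological plus measurement) simulator for end-to-end
    testing without experimental data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
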