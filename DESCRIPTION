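Package: rva
Title: Replicate Variation Analysis of Omics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies acute-stress-induced canalization of metabolomic and
    proteomic variation by profiling per-feature coefficient-of-variation (CV)
    distributions across biological replicates and comparing them between
    experimental groups (two-sample Kolmogorov-Smirnov d and p, Wilcoxon
    tests, mean/median CV shifts). Includes temporal recovery tracking against
    an unstressed reference, mean-variance artifact diagnostics and PCA score
    plots, a two-level power simulation relating replicate number, feature
    number and SD-to-mean ratio to the accuracy of a measured CV distribution,
    and a synthetic-data generator with known ground-truth canalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
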