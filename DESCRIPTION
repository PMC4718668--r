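Package: cgenet
Title: Coordinated Gene Expression Network Analysis for Regional
    Immediate-Early-Gene Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-group functional networks from subject-level
    regional immediate-early-gene (IEG) expression by intersubject Pearson
    correlation, thresholds edges by correlation significance, detects
    modular community structure of the resulting weighted signed networks,
    and statistically compares drug-activated networks against baseline
    networks edge-by-edge with Fisher r-to-z difference scores under false
    discovery rate control, classifying significant changes as gains or
    losses of positive or negative coordinated expression. Includes a
    synthetic-data generator that plants block correlation structure and
    group-specific edge perturbations so every stage of the pipeline can be
    validated against known ground truth, deterministic pseudoanatomical
    network renderings, graph exports, and an end-to-end pipeline driver
    with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
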