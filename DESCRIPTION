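Package: cytofp
Title: Cytometric Fingerprinting of Microbial Community Dynamics
Version: 0.1.0
Authors@R: person("cytofp", "developers", role = c("aut", "cre"),
    email = "cytofp@example.org")
Description: Gate-based analysis of microbial community flow cytometry
    fingerprints. Provides a synthetic single-cell event simulator for
    replicated treatment time series, polygon gate templates (manual files
    or kernel-density peak detection), relative cell-abundance extraction,
    gate-based Hill alpha-diversity and unique-gate intra-community
    beta-diversity, Bray-Curtis/NMDS community trajectories, per-gate trend
    slopes and Spearman response flagging, and a reproducible end-to-end
    pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
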