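Package: proteoBridge
Title: Cross-Platform Proteomic Bridging, Imputation and Fidelity Tiering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Harmonizes paired affinity-proteomics matrices from an
    aptamer-based (RFU-scale) and a proximity-extension (NPX-scale)
    platform, trains bi-directional per-protein gradient-boosted
    imputation models, scores every overlapping protein with a
    four-tier measurement-fidelity index built from baseline and
    post-imputation Pearson concordance, attributes imputation success
    to feature neighborhoods via permutation importance and first-K
    retraining curves, and runs tier-informed replication analyses
    (penalized continuous-outcome modeling and per-protein
    proportional-hazards scans). Ships a paired-platform simulator
    with known per-protein fidelity classes, below-LOD censoring and
    linked continuous and time-to-event phenotypes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    xgboost,
    glmnet,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
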