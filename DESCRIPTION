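Package: l1census
Title: Census Analyses for Neocortical Layer 1 Interneurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for a census of neocortical layer 1
    GABAergic interneurons recorded with patch clamp and reconstructed in 3D.
    Classifies firing patterns into Petilla-style electrophysiological types from
    inter-spike-interval regression rules, extracts a 44-feature morphometric
    battery from SWC reconstructions with supervised (LDA) and unsupervised (PCA)
    cluster validation including a label-randomization cross-validation test,
    analyses paired recordings for IPSP kinetics, GABA-A/GABA-B receptor-type
    classification and gap-junction coupling, and aggregates circuit-level
    connection statistics. Ships seeded synthetic-data generators for every input
    so the whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
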