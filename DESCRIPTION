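Package: csmol
Title: Conformational-Space Similarity Descriptors and Contrastive Molecular Representation Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An open toolkit for conformational-space similarity (CSS) profiling
    of small molecules. Generates conformer ensembles under global and
    near-native strain-energy schemes, scores ensemble-vs-ensemble 3D
    shape/pharmacophore similarity into raw and advanced CSS descriptors,
    computes element-agnostic maximum-common-substructure similarity, builds
    scaffold-split contrastive training datasets, trains a message-passing
    graph encoder with projection heads against CSS labels, and applies the
    learned encodings to zero-shot virtual screening, target identification,
    and downstream property (QSAR/ADMET) modeling. Includes deterministic
    synthetic fixtures, ranking metrics (BEDROC, AUROC, enrichment factor),
    and fingerprint baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: OpenBabel (obabel, obenergy on PATH)
Config/testthat/edition: 3
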