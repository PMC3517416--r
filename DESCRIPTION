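Package: pepclip
Title: Cross-Species Urinary Peptidomics and Protease Activity Inference
Version: 0.1.0
Authors@R: person("pkg", "maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for capillary-electrophoresis mass-spectrometry
    (CE-MS) urinary peptidomics studies. Clusters per-sample peak lists into
    consensus peptides with mass- and migration-time-dependent tolerance
    windows, screens differential peptide markers by Wilcoxon rank-sum tests
    with Benjamini-Hochberg correction, validates sequenced peptides against
    theoretical mass and predicted CE migration time, classifies rat-to-human
    peptide orthology into three tiers based on cleavage-site identity and
    region overlap, and infers protease activity directions from
    cleavage-site motif matches against a bundled MEROPS/CutDB-derived motif
    table. Includes a seeded synthetic-study generator producing two-species
    case/control peptide datasets with planted fold changes and planted
    protease cleavage asymmetries for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
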