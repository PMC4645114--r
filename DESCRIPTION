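Package: ensembleVS
Title: Ensemble Virtual Screening with Bayesian Score Fusion
Version: 0.1.0
Authors@R: person("ensembleVS", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Toolkit for structure-ensemble virtual screening campaigns against
    a single protein target. Qualifies candidate receptor structures by
    redocking accuracy and active/decoy score separation, derives
    receptor-ligand pharmacophore models and conformer fit values, fuses
    per-structure docking scores and pharmacophore fit values with a
    Laplacian-corrected naive Bayesian classifier, and post-processes the
    ranked library with drug-likeness filters, fingerprint clustering and
    scaffold substructure search. Includes a deterministic synthetic fixture
    generator so the whole funnel is testable without external docking
    software or compound databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
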