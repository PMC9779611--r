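Package: tickfold
Title: Structure-Aware Annotation of Tick Salivary Protein Families
Version: 1.0.0
Authors@R:
    person("Tickfold", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for structure-aware annotation of secreted tick
    salivary proteins. Reads predicted protein structure models (PDB
    format with per-residue pLDDT in the B-factor column), protein
    sequences (FASTA) and tabular structural-search hit tables, and
    provides disulfide-connectivity assignment from sulfur-sulfur
    distances, PROSITE-syntax motif scanning, Z-score based
    remote-homology family reassignment rules, RGD/KGD disintegrin
    hairpin detection, coarse C-alpha secondary-structure assignment,
    Kabsch superposition, and per-family RMSD fingerprint statistics.
    Includes deterministic synthetic-fixture generators for every input
    kind and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
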