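Package: cpikit
Title: Characterization of Plant Carboxypeptidase Inhibitor Peptide Families
Version: 0.1.0
Authors@R: person("cpikit", "maintainers", email = "cpikit@example.org",
    role = c("aut", "cre"))
Description: Sequence curation, threshold consensus and cysteine-spacing
    motif discovery, physicochemical panels (molecular weight, isoelectric
    point, charge, hydrophobic ratio, Boman index), distance-based
    phylogenies with bootstrap support, and geometric typing of
    inhibitor-enzyme interface contacts for cysteine-rich
    carboxypeptidase-inhibitor peptides, together with a seeded synthetic
    family generator that makes every pipeline stage testable without
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
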