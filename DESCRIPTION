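Package: plpscreen
Title: Reverse-Docking Enzyme Screening by Catalytically Favorable
    Conformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for "one substrate, many enzymes" reverse-docking
    screens of pyridoxal 5'-phosphate (PLP) dependent enzymes and
    aldehyde dehydrogenases. Builds the covalent PLP external aldimine
    of a substrate, prepares an enzyme set (oligomer assembly by
    superposition, catalytic-residue location, docking-grid placement),
    parses docked pose ensembles, scores poses by the Dunathan
    stereoelectronic criterion (bond-to-ring-plane angles chi1/chi2/chi3
    and the catalytic distance), clusters poses by RMSD, ranks enzymes
    by seven cluster metrics including the number of catalytically
    favorable conformations in the catalytic cluster (CC-CFC), validates
    rankings by ROC/AUROC, and fits Michaelis-Menten and competitive
    inhibition kinetics with propagated errors. Includes seeded
    synthetic-fixture generators so the full pipeline runs without
    external downloads or a docking engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ChemmineR,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Open Babel (obabel) for substrate preparation
Config/testthat/edition: 3
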