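Package: foldsite
Title: Binding-Site Confidence and Docking-Pose Assessment for Predicted
    Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assessment toolkit for predicted macromolecular models of the
    kind produced by AlphaFold-style structure predictors and homology
    modelling servers, developed around the homotrimeric human P2X7
    receptor.  Extracts per-residue pLDDT confidence from the B-factor
    channel of PDB/mmCIF files and aggregates it over binding-site key
    residues and their sequence neighbours; computes optimal rigid-body
    (Kabsch) superpositions and all-pairs C-alpha RMSD matrices; validates
    redocking poses with symmetry-corrected ligand RMSD solved per element
    by the Hungarian assignment method against the conventional 2 Angstrom
    criterion; derives docking grid boxes from ligand geometric centers;
    and profiles protein-ligand contacts (hydrogen bonds, salt bridges,
    hydrophobic contacts, pi-stacking) into per-residue interaction
    fingerprints.  A synthetic-structure generator with analytic ground
    truth supports property-based testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
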