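Package: ptmligand
Title: Binding-Site-Proximal PTM Annotation and Ligand Pose Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing post-translational modification (PTM) sites
    in the structural context of bound small molecules. Reads protein-ligand
    complexes (PDB/mmCIF), maps chain residues to reference (UniProt-style)
    numbering by global sequence alignment, identifies PTM sites within a
    distance cutoff of any ligand atom, and assigns sites to protein domain
    ranges. Evaluates predicted or PTM-modified models against a reference
    complex by sequence-guided rigid-body superposition with iterative
    outlier rejection, no-fit ligand RMSD with atom-name harmonization
    against canonical component atom orders, and a superposition-free
    protein-ligand interface conservation score (lDDT-PLI). Includes a
    synthetic-fixture generator with analytically known proximity sets,
    RMSDs and interface scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ChemmineR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
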