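Package: plaff
Title: Persistent-Laplacian Interface Features for Protein-Protein Binding
    Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts multiscale topological and physicochemical descriptors
    of protein-protein binding interfaces and regresses binding free energy
    on them. Interfaces are read from PDB structures, split into two binding
    partners, and encoded through bipartite Vietoris-Rips filtrations on a
    modified cross-partner distance function. Persistence barcodes are
    computed by boundary-matrix reduction over Z2, and persistent Laplacian
    spectra (harmonic and non-harmonic) are summarised into binned
    eigenvalue statistics per element pair. Auxiliary blocks cover solvent
    accessible and buried surface area, Coulomb and Lennard-Jones
    interaction energies, a screened-electrostatics slot, and pooled
    per-residue sequence embeddings. Regression heads are a multilayer
    perceptron trained with Adam and early stopping, and a gradient-boosted
    tree baseline, evaluated under grouped and leave-one-protein-out
    cross-validation so mutants never separate from their parent complex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    xgboost,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
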