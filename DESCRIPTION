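Package: mimotree
Title: Mapping Phage-Display Mimotopes onto Antigen Structures to Predict
    Conformational Epitopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts antibody-binding (conformational) epitopes on an antigen
    three-dimensional structure from a set of phage-display mimotope peptides.
    A depth-first search maps contiguous mimotope segments ("seeds") onto an
    adjacency graph of solvent-exposed antigen residues using a weighted
    physicochemical property distance between amino acids, bridges mimotope
    gaps under an extended-chain geometric bound, and reports the union of
    perfect-match and longest near-match seed connections. Also provides the
    buried-surface-area definition of the true epitope from an
    antigen-antibody complex, residue-level evaluation statistics
    (sensitivity, precision, Matthews correlation, hypergeometric enrichment,
    signed-rank comparisons), ensemble combination rules for merging
    predictions from several methods, and a deterministic synthetic-fixture
    generator with planted epitopes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
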