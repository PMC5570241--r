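Package: modqa6
Title: Hybrid Pure/Quasi-Single Protein Model Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the accuracy of 3D protein models (EMA/QA) without the
    native structure, combining pure-single scores computed from the model and
    sequence-based predictions (contact distance agreement, secondary structure
    agreement, an optional external local score channel) with quasi-single
    scores computed against a reference ensemble of models for the same target
    (superposition-based distance similarity, local Q-scores, disorder
    agreement). A sliding-window neural network fuses the six per-residue score
    tracks into a consensus local similarity which is converted to a predicted
    per-residue error in Angstroms; global quality scores, optimized score
    combinations for correlation and ranking, and a calibrated P-value for the
    chance that a model is unrelated to the native fold (TM-score < 0.2) are
    reported. Includes structural primitives (Kabsch superposition, iterative
    TM-score alignment, Kabsch-Sander secondary structure assignment), parsers
    for PDB, PSIPRED ss2, DISOPRED and CASP RR inputs, CASP QA and B-factor
    annotated PDB output, and a deterministic synthetic fixture generator
    (ideal-geometry natives, decoy ladders, matching prediction files) so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
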