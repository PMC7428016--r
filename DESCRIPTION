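Package: drfkit
Title: Directional Reactivity Factors for Ligand-Receptor Potency Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the directional reactive (DR) model for screening
    receptor-mediated potency of small aromatic ligands. Computes directional
    reactivity factors (DRF) from molecular geometry, condensed Fukui
    functions derived from charge populations of the neutral, anion and
    cation states, and the ligand dipole moment; computes receptor net charge
    at a given pH from amino-acid composition via Henderson-Hasselbalch
    fractions; fits four-parameter log-logistic dose-response curves to
    estimate EC50 under an equal-efficacy/parallelism assumption; and
    provides ranking and correlation statistics against bioassay-derived
    potencies, including packaged transcriptions of published reference
    tables for the twelve chrysene homologues. Ships deterministic synthetic
    fixture generators (idealized fused-ring geometries, planted Fukui
    vectors and dipoles, noisy dose-response curves) and an independent
    brute-force scoring oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
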