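Package: confrag
Title: Confidence-Guided Filtering of Protein Fragment Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing the reliability of local protein structure
    prediction from position-specific fragment libraries. Fragments covering
    each target residue are clustered into a graph weighted by pairwise
    Calpha-RMSD, a greedy outlier-rejection algorithm shrinks each cluster to
    stability, and a confidence score combining motif recurrence and
    structural consistency flags residues where the cluster centroid yields
    a reliable backbone torsion angle (phi, psi) prediction. Includes
    wraparound angular error metrics, local precision and coverage
    statistics, an optimal-centroid baseline, and a seeded generator of
    synthetic targets and fragment libraries with planted conserved motifs
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
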