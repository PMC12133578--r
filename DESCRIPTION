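Package: celiaclens
Title: Single-Cell, Spatial and TCR Repertoire Statistics for the Celiac
    Intestinal Mucosa
Version: 0.1.0
Authors@R:
    person("Mucosa", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for dissecting the celiac disease lesion
    from single-cell and spatial transcriptomics together with T cell
    receptor repertoires. Implements KNN-neighborhood differential
    abundance between disease states (healthy control, active and treated
    celiac disease), cluster proportion tests, centroid-tree pseudotime
    with branch-proportion readouts, repertoire statistics (Morisita-Horn
    overlap, negative-binomial V-segment usage tests, expansion quintiles,
    CDR3 composition, motif and sharing analysis), Visium-style spot
    lattice region analysis (adjacency networks, NNLS signature
    deconvolution, colocalization), receptor-ligand permutation scoring
    and susceptibility gene-set enrichment. Ships negative-binomial
    synthetic generators with ground truth for cells, repertoires and
    spot lattices, so every statistic is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Matrix,
    MASS,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
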