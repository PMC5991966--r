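Package: allostruct
Title: Conformational Ensemble Analysis and Allosteric Site
    Characterization for Small GTPases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for crystallographic conformational
    ensembles of small GTPases such as Rab11. Builds a common C-alpha
    residue frame across an ensemble of chains, superposes the members on
    their most structurally invariant core, and quantifies flexibility
    (RMSF), region-wise structural deviation (pairwise RMSD), and
    correlated residue motions (dynamical cross-correlation matrices).
    Representative structures are selected as clustroids of hierarchical
    clusterings in low-dimensional embeddings obtained by principal
    component analysis, FastICA and locally linear embedding. Residue
    interaction networks (7 Angstrom C-alpha contact graphs with
    distance-weighted edges) provide betweenness centralities and
    shortest communication paths from candidate allosteric sites to the
    nucleotide site. Docking hit tables are re-scored with an 80/20
    energy/interaction weighting backed by a geometric protein-ligand
    interaction profiler, and binding-site conservation is compared by
    global sequence alignment over site residue sub-selections. A
    synthetic-data module generates ensembles with planted modes,
    clusters, correlations and interactions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    bio3d,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
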