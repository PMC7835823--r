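Package: trajgeom
Title: Geometry, Collective Motion and Shape-Space Statistics of
    Molecular Dynamics Trajectories
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for protein molecular dynamics (MD)
    trajectories centred on thioredoxin-fold proteins and the vitamin K
    epoxide reductase luminal loop: least-squares superposition, RMSD and
    RMSF profiles with a high-fluctuation exclusion rule, covariance and
    principal component analysis of collective motion, dynamic
    cross-correlation, ensemble-based conformational clustering with
    cut-off scans and merged-replica composition, CXXC motif geometry and
    Klyne-Prelog classification, tetrahedron-edge and helix-drift
    geometry, Kendall shape-space statistics of atomic landmarks (geodesic
    distances, metric multidimensional scaling, Frechet means, the
    triangle disk), hydrogen-bond, salt-bridge and hydrophobic contact
    detection with interface analysis, and a Kabsch-Sander style
    secondary-structure assignment. Includes synthetic-trajectory
    generators with planted ground truth (Gaussian ensembles with a
    prescribed covariance spectrum, multi-state switching, ideal helices,
    landmark motifs, planted interfaces) and a configuration-driven
    pipeline producing CSV/JSON report bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
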