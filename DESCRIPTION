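Package: cetpdyn
Title: Structural Dynamics Descriptors for CETP-Like Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for conformational ensembles of two-domain
    tunnel proteins such as the cholesteryl ester transfer protein (CETP).
    Reads single- and multi-model PDB files and plain XYZ trajectories,
    computes the geometric descriptors used to characterise lipid-passage
    openings (maximum inter-residue gate distances, side-chain orientation
    angles, domain bend angles, RMSD/RMSF/radius of gyration), partitions
    Shrake-Rupley solvent-accessible surface area into hydrophobic and
    hydrophilic contributions per flexible region, detects interior cavities
    with alpha-spheres built on a Delaunay tetrahedralization and classifies
    tunnel continuity, performs essential-dynamics PCA and dynamic
    cross-correlation analysis of C-alpha fluctuations, and aggregates
    MM/GBSA binding free-energy components (Coulomb, Lennard-Jones,
    generalized-Born polar solvation, surface-area nonpolar term) over
    trajectory snapshots. Ships deterministic synthetic-ensemble generators
    (hinge motions, fragmenting cavity cages, block-correlated motions, toy
    host-guest binding systems) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
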