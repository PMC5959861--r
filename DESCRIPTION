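Package: cntmd
Title: Post-Analysis of Molecular Dynamics Trajectories for Nanotube-Immobilized Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular dynamics trajectories of membrane
    receptors adsorbing onto single-walled carbon nanotubes. Provides
    superposition and RMSD series, Shrake-Rupley solvent-accessible surface
    area and receptor-nanotube contact area, 6 Angstrom adsorption metrics,
    dynamical cross-correlation matrices, protein structure networks with
    allosteric shortest-path search and path frequencies, an MM-PBSA-style
    binding-energy ledger with per-residue decomposition, grid-based pocket
    volumes, water density grids and axial hydration profiles, and
    virtual-screening selectivity statistics (descriptor trends, top-fraction
    subsets, ROC/AUC, class comparisons). Includes seeded synthetic-data
    generators with recorded ground truth for every pipeline input, and a
    staged command-line pipeline with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
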