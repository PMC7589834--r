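Package: vardyn
Title: Consensus Missense-Variant Screening and Comparative Protein
    Dynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prioritizing deleterious missense variants
    (nsSNPs) by consensus over multiple predictor score tables, and for
    quantifying how a variant alters a protein domain's conformational
    dynamics from multi-model PDB trajectories: RMSD/RMSF/radius of
    gyration, solvent-accessible surface area (Shrake-Rupley),
    intramolecular hydrogen-bond counts, dynamic cross-correlation maps,
    essential-dynamics PCA, dynamic residue interaction networks
    (betweenness centrality and average shortest path), simplified
    Kabsch-Sander secondary-structure timelines, and free-energy
    landscapes over (RMSD, Rg) reaction coordinates. Includes synthetic
    trajectory and score-table generators with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
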