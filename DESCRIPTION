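Package: idpensemble
Title: Conformational Ensemble Analysis for Intrinsically Disordered Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing conformational ensembles of short
    intrinsically disordered peptides, built around a 15-residue
    mitochondrial localization peptide and its complete single-position
    substitution panel. Provides a synthetic ensemble generator with
    controllable per-residue Ramachandran-basin propensities, backbone
    reconstruction from internal coordinates, compactness metrics (radius
    of gyration, end-to-end distance, Shrake-Rupley solvent accessible
    surface area), five-region Ramachandran classification with
    per-residue occupancy and deviation statistics, PCA-based multivariate
    variant comparison and ranking, and a desk-scale well-tempered
    metadynamics engine with time-resolved free-energy reconstruction and
    convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    bio3d,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
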