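Package: e2dyn
Title: Cross-Variant Essential Dynamics Comparison for Protein Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare the essential dynamics of homologous protein
    conformational ensembles, built around the analysis of E2
    ubiquitin-conjugating enzyme variants. Provides multiple-sequence-alignment
    mapped principal component analysis of multi-replicate ensembles, subspace
    comparison via the root mean square inner product (RMSIP) with an
    eigenvalue crossing-over diagnostic and cosine-content sampling checks,
    Shrake-Rupley solvent accessible surface areas, side-chain distance and
    salt-bridge/hydrogen-bond persistence analysis, sequence-motif
    classification at the conserved E2 Ser/Asp (CES/D) catalytic-cleft site,
    and an exponential activity-distance model. A synthetic-ensemble generator
    with prescribed eigen-spectra and controlled subspace perturbations makes
    the whole pipeline testable without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'activity_model.R'
    'alignment_mapping.R'
    'e2dyn-package.R'
    'essential_dynamics.R'
    'geometry_analysis.R'
    'pipeline.R'
    'structure_io.R'
    'subspace_compare.R'
    'synthetic_data.R'
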