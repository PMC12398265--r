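Package: confshift
Title: Conformational-Transition Trajectory Analysis for Multi-Domain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of
    multi-domain proteins that interconvert between compact (ring-like) and
    extended (hook- and sigmoid-like) conformations, as beta-2-glycoprotein I
    does. Provides Hausdorff path-similarity between repeat trajectories,
    coordinate principal-component analysis with hierarchical clustering into
    conformational states, per-residue Shrake-Rupley solvent-accessible
    surface area with per-region percent-difference tables against a
    reference state, windowed RMSF, dynamic cross-correlation matrices,
    inter-region distances and contact probabilities, rigid-body orientation
    scanning with a flat-bottom restraint energy, and residue-class motif
    scanning for amphipathic epitope patterns. A synthetic-trajectory
    generator plants conformational states, exposure changes and correlated
    motions so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
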