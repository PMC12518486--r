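Package: radssm
Title: Statistical Shape Modelling and Shape Completion for the Distal Radius
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds statistical shape models (SSMs) of the radius from
    corresponded triangulated surface meshes and extends them with an
    isotropic Gaussian-process kernel into a shape completion model that
    predicts the distal 12% of the bone from its proximal 88%, as used in
    3D preoperative planning of corrective osteotomies for distal radius
    malunion. Includes triangle-mesh input/output (PLY, STL, OBJ),
    a synthetic radius population generator with known latent shape modes,
    anatomical coordinate-frame construction from landmarks, rigid and
    low-rank Gaussian-process nonrigid iterative-closest-point registration,
    generalized Procrustes analysis, hyperparameter grid search, the
    standard SSM quality metrics (accuracy, compactness, generalization,
    specificity, Hausdorff distance, per-vertex heatmaps), and decomposition
    of the prediction error into clinical six-degree-of-freedom measures
    (radial inclination, volar tilt, axial rotation, dorsal shift, radial
    shift, lengthening).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
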