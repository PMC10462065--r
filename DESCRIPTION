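Package: gpcrtraj
Title: Geometric State Analysis of GPCR Trajectories
Version: 0.1.0
Authors@R: person("gpcrtraj", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify transmembrane-helix arrangement and
    intracellular-loop conformational states in molecular dynamics
    trajectories of G-protein-coupled receptors. Implements Kabsch
    superposition, per-frame geometric metrics (helix vertical shift,
    inter-helix distances, loop rotation angle, backbone RMSD collective
    variables, G-protein helix-5 displacement), geometric hydrogen-bond and
    water-bridge detection with fraction-of-frames frequency tables, a
    two-threshold rotational-state classifier for the second intracellular
    loop (ICL2) with replica occupancy statistics, backbone dihedral
    principal component analysis, and a synthetic-trajectory generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
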