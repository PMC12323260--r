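Package: shakediff
Title: Exact Geometric Constraints in Score-Based Diffusion Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enforcing holonomic geometric constraints (interatomic
    distances, bond angles, torsions) exactly during score-based diffusion
    sampling of molecular conformations. Constraint residuals and analytic
    gradients feed an iterative Lagrange-multiplier (SHAKE-type) projection
    that returns every stochastic trial step to the constraint manifold, with
    optional tangent-space projection of the noise increment. Time-dependent
    bounds follow a sigmoid schedule so sampling starts unconstrained and
    tightens to strict equality. A harmonic-restraint guidance baseline, a
    reverse-SDE sampler with analytic toy scores, a clustering/PCA pipeline
    that mines consistent distance-constraint sets from conformer ensembles,
    internal-coordinate chain builders (including a butane fixture), and
    XYZ/SDF/YAML input-output round out the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR
Config/testthat/edition: 3
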