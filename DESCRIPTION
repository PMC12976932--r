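Package: pursuitgeom
Title: Population Geometry of Multi-Agent Spatial Coding in a Pursuit Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how neural populations encode the positions
    of multiple agents (self avatar, prey, predator, gaze) during a
    joystick-controlled prey-pursuit task. Provides an agent-based task and
    Poisson spike-train simulator with plantable population geometry,
    occupancy-binned smoothed spatial rate maps, a Poisson linear-nonlinear
    GLM with spatial smoothness regularization and forward stepwise model
    selection on cross-validated log-likelihood, the SPAEF map-similarity
    index with permutation nulls and noise ceilings, agent-preference indices
    with Hartigan dip tests, population-subspace analyses (alignment index,
    covariance-matched random-subspace nulls, mutually orthogonal subspace
    optimization on the Stiefel manifold, cross-subspace linear maps), and
    cross-condition generalization performance (CCGP) decoding with decoding
    axis geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
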