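Package: motorload
Title: Population Analysis of Contralateral and Ipsilateral Load
    Responses in Motor Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured motor-cortex recordings
    during mechanical load perturbations of either limb. Provides a synthetic
    Poisson-spiking session generator with controllable ground truth,
    post-spike-potential kernel smoothing, per-neuron load-sensitivity ANOVA
    and planar preferred-load fits with Rayleigh bootstrap statistics,
    response-onset detection, pairwise correlation-change statistics against a
    trial-split null, and population subspace analyses: per-context PCA, the
    alignment index with a variance-weighted random-subspace null, joint
    orthogonal-subspace optimization on the Stiefel manifold, and
    projection-difference statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
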