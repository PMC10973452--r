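Package: velodelta
Title: Differential Single-Nucleus RNA Velocity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and group-wise comparison of RNA velocity from
    spliced and unspliced single-nucleus RNA-seq counts. Implements
    steady-state and stochastic (second-moment) velocity estimators on a
    k-nearest-neighbour moment graph, differential velocity and expression
    testing with a subject-level permutation null for the Wilcoxon rank-sum
    statistic, whole-transcriptome cell-speed and residual velocity-field
    comparison in a 2D embedding, covariate-adjusted partial Spearman
    association of subject-mean velocities with neuropathology traits, and
    Fisher's exact cross-dataset overlap validation. Includes a kinetic
    (transcription-splicing-degradation) cohort simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
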