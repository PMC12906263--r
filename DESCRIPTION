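Package: strideworks
Title: Stride-Level Running Kinematics, Coordination Variability and 1D
    Permutation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@strideworks.dev",
    role = c("aut", "cre"))
Description: Tools for analysing how running technique changes during a
    treadmill run to exhaustion. Provides a synthetic treadmill-gait
    generator with known ground truth (two technique clusters, progressive
    fatigue drift, stride-to-stride variability, batched recording gaps),
    zero-lag Butterworth filtering, kinematic foot-strike/toe-off detection,
    stride slicing with 201-point time normalisation, spatiotemporal
    features (duty factor, leg-length-normalised stride frequency),
    ensemble joint-angle curves, angular-velocity ellipse-area coordination
    variability, and nonparametric statistical parametric mapping: a
    permutation-based two-way mixed-design repeated-measures ANOVA over
    kinematic continua with suprathreshold-cluster inference, alongside
    conventional 0D repeated-measures ANOVA, Bonferroni post hocs with
    Cohen's d, and Shapiro-Wilk-gated baseline group comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
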