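Package: sigmalog
Title: Sigma-Lognormal Decomposition and Fatigue Screening for Handwriting Kinematics
Version: 0.1.0
Authors@R:
    person("Scribens", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing rapid pen movements recorded on a digitizing
    tablet under the kinematic theory of rapid human movements. Planar velocity
    profiles are modelled as vector sums of lognormal impulse responses; the
    package provides the closed-form forward model, a greedy extractor that adds
    lognormal components until a signal-to-noise reconstruction target is met, a
    seeded synthetic-session generator emulating simple strokes, triangles and
    target-to-target oscillations, role and phase classification with artifact
    and outlier filtering, and a nonparametric statistical battery (Mann-Whitney,
    permutation Hotelling T2, Wilcoxon signed-rank, Cohen's d, Spearman
    correlations) for pre- versus post-fatigue comparisons at the individual and
    group level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
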