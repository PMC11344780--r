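Package: dyadgame
Title: Simulation and Analysis of Dyadic Joint Ball-Steering Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse a cooperative two-player
    ball-steering game in which a dyad jointly navigates a ball through
    landscapes of targets and partly invisible obstacles. Provides a
    deterministic 60 Hz game engine, coupled steering agents with known
    ground-truth coupling for synthetic cohorts, interpersonal movement
    coordination measures (windowed lagged cross-correlation and its
    peak-picked statistics, mutual information, phase slope index,
    surrogate-dyad baselines), gaming-behaviour measures, and the
    statistical pipeline used to relate them to experience ratings:
    linear mixed models with a pair random intercept and AR(1) residual
    correlation fitted by REML with backward elimination and
    leave-one-pair-out validation, repeated-measures correlation,
    bootstrap ANOVA-type tests (ATS/MATS), and grouped
    Benjamini-Hochberg false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
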