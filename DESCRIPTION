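Package: smadtier
Title: Tiered Modeling and Trajectory Analysis of Heterogeneous TGF-beta/SMAD Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze heterogeneous single-cell TGF-beta/SMAD signaling
    dynamics: a mechanistic ordinary-differential-equation model of receptor
    trafficking, SMAD phosphorylation and transcriptional negative feedback with
    event-driven stimulus protocols; chi-square multistart parameter estimation
    at population and subpopulation resolution; constrained dynamic time warping
    (cDTW) with hierarchical clustering of nuclear-to-cytoplasmic SMAD ratio
    trajectories into signaling classes; single-cell ensemble simulation with
    correlated and uncorrelated log-normal protein-level noise and calibration
    of noise magnitudes against signaling-feature distributions; and
    heterogeneity statistics (local density scores, mutual-information
    fractions, sister-cell divergence with bootstrap effect sizes). A synthetic
    trajectory generator emulates live-cell imaging datasets so the full
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    withr,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
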