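Package: fibdamage
Title: Quantifying Focused-Ion-Beam Damage in Cryo-ET Lamellae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for profiling structural damage introduced by (plasma)
    focused-ion-beam milling of cryo-ET lamellae. Interpolates sparse manual
    annotations of the two milling surfaces into continuous boundary sheets,
    computes per-particle shortest distances to those sheets and local lamella
    thickness, groups particles into depth and backside-distance cohorts with
    tomogram-matched random controls, estimates Rosenthal-Henderson B-factors
    from subset-size resolution series with standard-error propagation, and
    characterises the depth dependence of the damage with weighted
    three-parameter exponential-decay fits. Includes Fourier shell correlation
    resolution estimation for half-map pairs, STAR/MRC/CSV input and output,
    and a synthetic-data generator that emulates slab-shaped lamella geometry
    and depth-dependent B-factor inflation so the whole pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
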