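Package: phylasym
Title: Phylogenetic Analysis of Brain Size Asymmetry from Linear Morphometrics
Version: 0.1.0
Authors@R: person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing directional asymmetry of bilateral brain
    structures across species while accounting for shared ancestry.  Converts
    linear measurements (length, width, height of left and right sides) into
    ellipsoid volume estimates, computes a signed relative asymmetry index,
    classifies species by direction of lateralization, and tests hypotheses
    with phylogenetic paired t-tests and phylogenetic generalized least
    squares (PGLS) regressions under a maximum-likelihood Pagel's lambda
    correlation structure with inverse-sample-size weighting.  Includes a
    synthetic-data module (Yule trees, Brownian-motion trait evolution,
    lognormal measurement noise) so the whole pipeline can be exercised and
    validated without access to raw field data, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
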