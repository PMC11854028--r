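Package: SpringCranio
Title: Radiation-Free Planning of Spring-Assisted Cranioplasty from 3D Surface Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds simplified skull shell models of scaphocephalic infants from
    radiation-free 3D head-surface scans using anatomical-landmark planes and
    population-averaged tissue thickness and suture geometry, and simulates
    spring-assisted cranioplasty expansion with a quasi-static, geometrically
    nonlinear viscoelastic shell finite-element model. Reports spring opening
    and cranial-shape metrics (biparietal and occipitofrontal diameters,
    cephalic index) at immediate post-operative and follow-up timepoints.
    Includes triangle-mesh surgery primitives (plane cutting, surface
    offsetting, hole filling, osteotomy carving), surface-distance thickness
    mapping, suture-plane morphometrics, deterministic synthetic phantom
    generators, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
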