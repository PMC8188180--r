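Package: oxygel
Title: Oxygen Transport and Consumption Modelling in Cell-Seeded Hydrogel Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models steady-state oxygen transport and cellular consumption in
    cylindrical cell-seeded agarose constructs cultured on an agarose bed under
    a layer of medium. Provides an axisymmetric finite-volume solver for the
    nonlinear diffusion-reaction equation with Michaelis-Menten consumption
    kinetics, an inverse estimator that recovers the per-cell oxygen consumption
    rate from a single central sensor reading, biochemistry helpers that turn
    DNA assay readouts into region-wise cell-density maps, spatial oxygen
    analytics (central oxygen, volume-weighted region means, volumetric
    frequency distributions, contour export), and a synthetic-data generator
    emulating fiber-optic point-sensor readings and biochemical assay tables
    for the supported study arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
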