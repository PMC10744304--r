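Package: neotissue
Title: Curvature-Driven Neotissue Growth Simulation in Porous Bone Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Level-set simulation of neotissue (cells plus extracellular matrix)
    filling the pores of additively manufactured calcium-phosphate bone scaffolds.
    The neotissue/void interface advances at a speed proportional to the positive
    local mean curvature, reproducing the circularization and size dependence of
    pore filling observed in vitro. Includes signed-distance generators for
    prismatic channel cross-sections (triangle, square, hexagon, circle) and
    gyroid (triply periodic minimal surface) scaffolds, filling-fraction and
    shape quantification, packaged channel-filling observations, a synthetic
    observation generator, and Bayesian (sequential model-based) calibration of
    the growth coefficient against observed filling percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
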