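Package: phytoind
Title: Phytoindication, Hemeroby and Divisive Classification of Vegetation Releves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantitative vegetation assessment from releve
    (plot x species projective cover) data: community indicator scores on
    the Didukh and Ellenberg ordinal scales with conversion of the scores
    to physical environmental quantities (productive soil moisture, pH,
    salt content, radiation balance and others), hemeroby and naturalness
    indices of anthropogenic transformation, TWINSPAN-style divisive
    classification with pseudospecies and phi-coefficient diagnostic
    species, principal component analysis of the per-plot environmental
    block, and water-body morphometry (shoreline length, surface area,
    volume) from a digital elevation model. Includes a niche-based
    synthetic community generator so every stage is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan
Config/testthat/edition: 3
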