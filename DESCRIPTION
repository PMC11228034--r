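Package: mbwire
Title: Wiring-Structure Analysis of Visual Inputs to Mushroom-Body Kenyon Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the wiring structure of bipartite connectomic
    circuits, developed around the visual pathway into the Drosophila mushroom
    body (visual projection neurons and local visual interneurons onto Kenyon
    cells). Builds thresholded synapse-count connectivity matrices from edge
    lists, tests them against marginal-preserving shuffle null models (PCA
    eigenvalue-spectrum tests, conditional-input z-score analysis, bilateral
    identical-input-pattern stereotypy tests), quantifies effective input
    dimensionality with the participation ratio, classifies connections as
    bouton-claw or en-passant from the spatial dispersion of their synapse
    locations, and estimates receptive fields of visual neurons from
    skeleton-to-ommatidial-column proximity with spherical convex hulls and
    Mollweide map projection. A synthetic-connectome generator produces wiring
    under labelled-line, biased-mixture, and random hypotheses, bilateral
    hemisphere pairs, synapse-location clouds, and hexagonal eyemaps with
    planted receptive fields, so every analysis runs end to end with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    cluster,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    arrow
Config/testthat/edition: 3
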