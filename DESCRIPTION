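Package: phenomaize
Title: Single-Plant Maize Phenotyping from Tilt-Calibrated RGB Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Portable image-analysis pipeline for single maize plants
    photographed hand-held against a dark backdrop. Calibrates camera tilt to
    an approximate orthographic front view using only the device's depression
    and rotation angles and the camera field of view (no scene markers),
    segments the plant with an excess-green classifier (or an externally
    supplied mask), skeletonizes the silhouette with a two-step
    distance-transform algorithm, decomposes the skeleton into a stem axis and
    individual leaves via overlaid shortest routes, and extracts 45
    morphometric traits (15 plant, 25 leaf, 5 stem) in physical units.
    Includes stepwise-regression models mapping image traits to destructively
    measured biomass, a four-metric segmentation evaluation harness, and a
    parametric synthetic plant renderer that provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
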