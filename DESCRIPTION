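Package: curvadh
Title: Nanostructure-Registered Ratiometric Quantification of Curved Adhesions
Version: 0.1.0
Authors@R: person("curvadh", "developers", email = "curvadh@example.org",
    role = c("aut", "cre"))
Description: Image-quantification pipeline for curvature-dependent integrin
    adhesions ("curved adhesions") on engineered nanostructure arrays and in
    three-dimensional fibre matrices. Provides lattice registration of
    periodic nanobar/nanopillar arrays, membrane-normalized end/side and
    pillar/annulus ratiometrics, ratiometric FRET tension readouts with
    moment-preserving auto-thresholding, object-based adhesion
    colocalization in 2D and 3D, surface-relative cell infiltration depth in
    fibre matrices, and a synthetic-image generator with recorded ground
    truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph,
    withr
Config/testthat/edition: 3
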