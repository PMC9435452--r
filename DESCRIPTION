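Package: mirrormorph
Title: Mirror-Based Quantification of Facial Surface Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies facial asymmetry from 3D stereophotogrammetric
    surface meshes by mirroring a capture across its midsagittal plane,
    registering the mirror onto the original with the iterative closest
    point algorithm, and summarising the signed inter-surface distance map
    as the mean absolute distance and the percentage of surface within
    clinical cut-offs. Includes a synthetic facial-capture generator with
    controlled lesion depth, growth and acquisition noise for validation,
    PLY/OBJ input and output, and longitudinal report tables for
    monitoring hemifacial atrophy in growing individuals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
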