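Package: oirquant
Title: Automated Quantification of Vascular Pathology in Oxygen-Induced
    Retinopathy Flat Mounts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fully automated scoring of the mouse oxygen-induced retinopathy
    (OIR) model from lectin-stained retinal flat-mount mosaics. Segments
    pathological preretinal tufts with a five-feature quadratic discriminant
    classifier (local/global normalized intensity, Laplacian-of-Gaussian
    response, and rotation-invariant uniform local binary patterns), delineates
    the full vascular network by adaptive mean (Bradley) thresholding, extracts
    the vessel skeleton with branch-point and length metrics, and measures
    avascular zones by a distance-to-skeleton criterion. All size parameters
    scale with the flat-mount diameter, so the pipeline runs without user
    interaction. Includes a seeded synthetic flat-mount generator with exact
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
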