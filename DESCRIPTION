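Package: paskin
Title: Quantitative 3D Photoacoustic and Ultrasound Analysis of
    Hypopigmented Skin Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for quantifying hypopigmented skin lesions
    (vitiligo, idiopathic guttate hypomelanosis) from co-registered 3D
    photoacoustic (PA) and ultrasound (US) scans: US-guided skin-surface
    detection, depth windowing, maximum-amplitude and peak-depth
    projection onto a uniform grid, automatic lesion segmentation by
    Otsu thresholding, and four scalar lesion metrics (mean PA
    amplitude, local amplitude SD, boundary slope, relative PA peak
    depth) with nonparametric group comparison. Includes a synthetic
    phantom generator with ground truth so the whole pipeline can be
    exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
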