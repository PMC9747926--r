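Package: hemseg
Title: Hemorrhage Segmentation in Mobile-Phone Retinal Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segmentation of retinal hemorrhages in low-quality fundus
    photographs such as those captured with smartphone-mounted retinal
    lenses. Implements K-means multiregion contrast enhancement (KMMRC)
    to correct uneven illumination, iterative NICK-thresholding region
    growing (INRG) to extract multishade hemorrhage blobs, ellipse
    axis-ratio vessel removal, HSV-feature support-vector-machine
    candidate classification with stratified cross-validation, and
    blob-level and image-level evaluation metrics. Includes a seeded
    synthetic fundus scene generator with exact ground-truth masks so
    every pipeline stage can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    grDevices,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
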