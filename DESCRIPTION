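Package: ctdose
Title: Automated Water-Equivalent Diameter and Size-Specific Dose
    Estimates from Axial CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the water-equivalent diameter (Dw) and the
    size-specific dose estimate (SSDE) from axial computed-tomography
    images. Patient body contours are segmented automatically by
    thresholding at -200 HU, labelling connected components, keeping the
    six largest filled objects and removing the CT table by its vertical
    centroid position; a legacy largest-object contour is provided for
    comparison. Includes a minimal single-frame DICOM reader/writer, AAPM
    Report 204 size-conversion factors, per-slice and per-series dose
    reports, a synthetic elliptical phantom generator with closed-form
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
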