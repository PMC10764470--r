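Package: pectseg
Title: Pectoral Muscle Removal for MLO-View Digital Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic identification and removal of the pectoral muscle in
    mediolateral-oblique (MLO) full-field digital mammograms. The pipeline
    binarizes the image with global (Otsu) thresholds, detects edges with the
    Canny algorithm, extracts the pectoral/breast interface as a per-row
    boundary curve, and bridges broken or noisy boundary segments with a
    robust penalized least-squares (Whittaker) smoother using generalized
    cross-validation and bisquare reweighting. Includes region-relative
    false-positive/false-negative error metrics with Table-style aggregation
    and two-sample Z/Welch-t comparisons, a deterministic synthetic phantom
    generator with analytic ground truth, minimal DICOM/PNG/TIFF input, and a
    batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
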