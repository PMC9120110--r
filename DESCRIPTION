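Package: rsomvasc
Title: Vascular Biomarker Analysis for Raster-Scan Optoacoustic Mesoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for raster-scan optoacoustic mesoscopy (RSOM)
    imaging of skin microvasculature: breathing-motion estimation and
    correction of raw A-line scans, dual-band (10-40 / 40-120 MHz)
    delay-and-sum volumetric reconstruction with detector-sensitivity
    weighting, skin-layer and pigmented-lesion segmentation by dynamic
    programming, vessel segmentation into skeleton and branch points, six
    vascular biomarkers (total blood volume, vessel density, average vessel
    length, tortuosity, fractal number, lacunarity), and cohort statistics
    (Mann-Whitney U, logistic combination, ROC/AUC). Includes a synthetic
    skin/vessel phantom generator and a band-limited optoacoustic forward
    model so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    signal,
    tiff,
    jsonlite,
    pracma,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
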