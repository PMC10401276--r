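Package: viscreen
Title: Vegetation-Index Screening for In-Season Corn Yield Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for in-season corn yield prediction from five-band UAV
    multispectral imagery. Computes a library of vegetation indices from
    plot-level reflectance, screens them against yield with a
    correlation-threshold stability-selection procedure and a cross-year set
    partition, cross-checks the screen with tuned random-forest permutation
    importance, and fits per-stage simple linear yield models scored by R
    squared and mean absolute percentage error. Includes radiometric
    calibration, supervised per-pixel background masking, zonal averaging over
    plot polygons, and a synthetic generator emulating a multi-year split-plot
    cover-crop experiment so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    mgcv,
    ranger,
    stats,
    tiff,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
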