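Package: fallsense
Title: Skeleton-Based Fall Detection from Head-Box Geometry and LSTM Sequence Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for fall detection from 2-D human pose keypoints.
    Derives a rotated square body bounding box from a head detection using
    Vitruvian body proportions, propagates it across frames with an offset
    vector so the detector need not be re-run every frame, cleans
    per-landmark coordinate trajectories with Tukey boxplot fences, and
    classifies fixed-length windows of shoulder/hip time series into
    walking, standing, sitting and falling with a from-scratch LSTM
    (explicit gate equations, analytic backpropagation, Adam). Includes a
    seeded synthetic motion generator for the four activities, evaluation
    utilities (confusion matrices, accuracy/sensitivity/specificity, 7:2:1
    splits) and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
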