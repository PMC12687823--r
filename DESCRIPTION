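Package: lensrecon
Title: Full-Shape Crystalline Lens Reconstruction from Multi-Incidence
    Anterior-Segment OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the complete three-dimensional shape of the human
    crystalline lens from segmented anterior-segment OCT acquisitions taken at
    multiple incidence (gaze) angles. Provides a synthetic eye-phantom forward
    simulator, iterative polynomial artifact rejection for segmented boundaries,
    Zernike-polynomial surface fitting, three-dimensional optical distortion
    correction by vector Snell ray tracing with group-index optical path
    conversion, iris-based rigid registration refined by trimmed iterative
    closest point, projection onto a principal-component (eigenlens) shape
    basis on a fixed polar grid, and quantification of equatorial diameter,
    volume and surface area together with repeatability and agreement
    statistics (coefficient of variation, Spearman rank correlation,
    Bland-Altman limits of agreement, Shapiro-Wilk normality screening).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    RANN,
    deldir,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
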