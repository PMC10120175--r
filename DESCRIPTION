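Package: refracto
Title: Standardized Refractive Surgery Outcome Graphs and Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-eye refraction and visual-acuity records into the
    journal-standard set of refractive-surgery outcome analyses: efficacy and
    safety indices, spherical and defocus equivalent accuracy, Alpins
    doubled-angle astigmatism vector analysis (TIA, SIA, correction index,
    angle of error), and SEQ stability over time. Computes the binned,
    annotated content of the ten standard panels for one or two groups with
    automatic parametric/nonparametric test dispatch and Cohen's d, renders
    them with ggplot2, and exports per-panel and composite TIFF figures.
    Includes a synthetic cohort simulator with controllable treatment models
    for validation and teaching.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    nortest,
    patchwork,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
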