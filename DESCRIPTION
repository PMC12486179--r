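Package: cysthead
Title: Quantitative Analysis of Subchondral Cystic Lesions in the Femoral Head
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for the morphometric analysis of
    subchondral bone cysts in volumetric micro-CT of the femoral head:
    threshold-based bone binarization, extraction of interior voids larger
    than 1 mm by morphological opening-by-reconstruction, landmark-driven
    six-region / three-pillar head segmentation, peri-cyst trabecular
    microarchitecture (BV/TV, BS/BV, Tb.Th, Tb.Sp, Tb.N, SMI, DA, Conn.D),
    2D bone histomorphometry (osteoid and eroded-surface panels, Weidner
    microvessel density), and a two-group comparison table with
    normality-routed parametric and non-parametric tests. Includes a
    synthetic femoral-head phantom generator with known ground truth so the
    whole pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    yaml,
    readr,
    RNifti,
    tiff,
    png,
    nortest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
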