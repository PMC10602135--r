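Package: procflow
Title: Quantification of Surgical Workflow from Step-Level Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying surgical workflow from step-level video
    annotations of robotic procedures. Provides an annotation data model
    with readers, writers and interval validation; per-step time and
    visit-frequency statistics with Spearman rank correlations against
    console and total operative time; first-order step-transition matrices
    with nodal/convergent/divergent step classification and chord-diagram
    (Circos tableviewer) matrix export; and a seeded Markov generator of
    synthetic annotated procedures calibrated to a 31-procedure robotic
    proctectomy reference cohort, so every pipeline stage is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
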