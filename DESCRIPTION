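Package: htppbmc
Title: Phenotypic Profiling Distances and Benchmark Concentrations for
    96-Well Cell Painting Screens
Version: 0.1.0
Authors@R:
    person("HTPP", "Pipeline Maintainers", email = "htpp@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput phenotypic profiling
    (Cell Painting) experiments run in 96-well plates: ingestion of
    cell-level morphological feature tables and plate maps, well-level
    quality filtering, three-step DMSO-referenced normalization
    (median/MAD at the cell level, well-median aggregation, DMSO-SD
    scaling), principal-component reduction, global and per-category
    Mahalanobis distances from the vehicle-control centroid, and
    concentration-response modeling of the distance metric with a
    ten-model family, AIC winner selection, continuous hitcalls,
    benchmark concentrations (BMC) with bootstrap confidence limits and
    exclusion rules. Includes a reference-placement background
    variability study for DMSO-only plates (row/column/whole-plate
    reference iterations and regression of distance on cell count), and
    a synthetic plate generator with implanted ground truth plus an
    analytic BMC oracle for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
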