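Package: tiicsig
Title: Multi-Dimensional Tumour-Infiltrating Immune Cell Analysis for
    Multiplex Immunohistochemistry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing per-cell tables exported from multiplex
    immunohistochemistry (m-IHC) image analysis of tumour tissue: boolean
    marker-combination phenotyping of tumour-infiltrating immune cells
    (TIICs), region- and compartment-resolved cell densities,
    nucleus-to-nucleus spatial statistics (effective score, effective
    density, nearest tumour-cell distance), a four-feature TIIC signature
    with an HR-weighted prognostic score, a repeated cross-validated
    multi-classifier harness for immunotherapy response prediction, and
    survival and cohort statistics. Includes a synthetic-study generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    data.table,
    FNN,
    jsonlite,
    yaml,
    survival,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
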