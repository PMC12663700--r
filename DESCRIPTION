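Package: msvdq
Title: Multisource Variability Metrics for Multicenter Questionnaire Data Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies inter-site coherence in multicenter questionnaire
    studies. Each site's responses (or missingness profile) are turned into a
    probability distribution over a shared bin grid; pairwise Jensen-Shannon
    distances are embedded as a geometric simplex by classical
    multidimensional scaling, and two bounded metrics are derived: the
    source probabilistic outlyingness (SPO) of each site relative to the
    case-weighted centroid, and the global probabilistic deviation (GPD)
    summarizing overall variability. Includes codebook-driven data
    validation, chained-equations ridge imputation, PCA/MCA dimensionality
    reduction with top-contributor ranking, per-site local-outlier-factor
    filtering, a branching-aware three-category missing-data model, and a
    synthetic multi-site questionnaire generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
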