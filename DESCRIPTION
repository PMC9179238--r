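Package: hrdcc
Title: High-Resolution Differential Cell Counts for Longitudinal Dairy-Cow Immunomonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of high-resolution differential cell
    counts (HRDCCs) in bovine milk and blood. Provides a synthetic
    longitudinal study generator (event-level flow cytometry plus serum
    biomarkers for a full lactation), a hierarchical gating engine with a
    fixed-threshold reference mode and a density-valley automated mode,
    FCS 3.1 input/output, longitudinal trend description (robust outlier
    flagging, cubic polynomial and four-knot spline fits), haptoglobin-
    defined inflammation episode detection, and multivariate lactation-
    phase analysis (PCA, sparse PLS discriminant analysis with
    one-vs-rest AUROC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    splines,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
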