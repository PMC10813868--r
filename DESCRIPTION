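Package: connqc
Title: Image-Quality Confounding in Structural and Functional Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify how magnetic-resonance image quality confounds
    associations between brain connectivity and demographic or clinical
    variables in population imaging cohorts. Implements per-scan quality
    metrics (inverse signal-to-noise ratio from back-to-back volumes, mean
    volume-to-volume head translation, and atlas-mask mismatch as one minus
    the Dice coefficient), construction of 94-region structural and
    functional connectomes, group-consensus proportional thresholding,
    graph measures (average node degree, weighted clustering coefficient and
    global efficiency) normalized against degree-preserving rewired null
    networks, and the two-model confounder-adjustment analysis with
    percent-change bookkeeping of standardized regression coefficients. A
    calibrated synthetic-cohort generator emulates the covariate
    distributions and the quality/connectivity regression structure of a
    large population study so the full pipeline is testable without access
    to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
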