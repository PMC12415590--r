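Package: idscn
Title: Individualized Differential Structural Covariance Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs individualized differential structural covariance
    networks (IDSCN) from regional gray-matter density: a covariate-adjusted
    partial-correlation reference network is estimated from controls, each
    patient's network perturbation is Z-scored edge-wise, and significantly
    altered edges are selected by Benjamini-Hochberg FDR. Downstream stages
    rank shared differential edges, subtype patients by k-means with
    silhouette-based model selection, compare subtypes edge-wise with
    covariate-adjusted tests and permutation validation, and screen
    imaging-clinical associations with VIF and residual-normality gates.
    Ships a synthetic cohort generator with planted covariance subtypes so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
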