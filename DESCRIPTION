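Package: circmir
Title: Circulating miRNA Signature Discovery from Low-Density qPCR Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for discovering and evaluating circulating
    microRNA signatures of vulnerable coronary artery disease from TaqMan
    low-density array (TLDA) cycle-threshold data. Provides Ct-matrix import
    with detection filtering and reference-gene (U6) normalization to
    2^-dCt relative expression, a two-class unpaired significance analysis
    of microarrays (SAM) with balanced label permutations and q-values,
    signature evaluation by hierarchical clustering, principal component
    classification, ROC analysis with Youden cut-offs and covariate-adjusted
    logistic regression, per-group Pearson coexpression networks with
    first-neighbor subnetworks and edge-overlap comparison, bead-calibrated
    microparticle enumeration from flow-cytometry event tables with
    MP-count-adjusted miRNA expression, and a synthetic cohort generator
    that emulates the statistical structure of plasma TLDA studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
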