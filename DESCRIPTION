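Package: clonetraj
Title: Clonal Trajectory Analysis for Paired Single-Cell Expression and TCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles antigen-experienced T-cell clonal populations from paired
    single-cell expression and TCR V(D)J data, classifies them (CD8/CD4/Treg),
    scores differentiation states with binned-control gene-set scores and
    cell-cycle phase calls, builds per-clone pseudotime trajectories through a
    low-dimensional embedding, and clusters clones by transcriptome-wide
    trajectory similarity using multivariate dynamic time warping, average-linkage
    hierarchical clustering and silhouette-maximising cluster-number selection.
    Ships a negative-binomial simulator of clonal differentiation patterns with
    known ground truth, including a centroid-confounded pattern pair, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    digest,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
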