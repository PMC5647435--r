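Package: wacna
Title: Weighted Analyte Correlation Network Analysis for Joint
    Transcript-Metabolite Modules
Version: 0.1.0
Authors@R:
    person("WACNA", "Maintainers", email = "maintainers@wacna.dev",
           role = c("aut", "cre"))
Description: Integrates transcriptomic and untargeted metabolomic
    abundance matrices into joint weighted correlation-network modules.
    Implements the upstream metabolomics feature quality control
    (pooled-QC relative standard deviation and detection filters),
    k-nearest-neighbour imputation, non-parametric differential
    abundance statistics with Benjamini-Hochberg correction and
    bootstrap fold-change confidence limits, per-dataset variance
    selection, soft-thresholded adjacency and topological overlap
    network construction, module detection by hierarchical clustering
    with an adaptive cut, module eigengenes, eigengene-design
    association for a two-factor diet by exercise design, generic
    hypergeometric over-representation analysis, a synthetic paired
    cohort generator with planted module structure, and recovery
    evaluation against the planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
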