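Package: ccsbiclust
Title: Condition-Dependent Correlation Subgroup Biclustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers biclusters in gene expression matrices as
    condition-dependent correlation subgroups: for each high-variability
    base gene, the search finds the gene-by-sample submatrix whose
    all-pairs Pearson correlation structure is specific to the selected
    samples, quantified by a condition-specificity score (BScore), and
    merges overlapping results. Includes a synthetic benchmark generator
    planting constant and shift-scale biclusters with ground truth,
    Recovery and Relevance match scoring against planted truth, and
    export of biclusters as condition-dependent coexpression network
    modules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
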