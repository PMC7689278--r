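Package: tempomics
Title: Perturbed Sub-Pathway Detection and Multi-Omics Mediator Discovery
    from Drug-Treatment Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies time-varying perturbed sub-pathways from control
    versus drug-treated time-series expression data via differential time
    vectors and lagged cross-correlation, embeds gene-centric multi-omics
    matrices (expression, copy number, methylation, mutation) into a
    low-dimensional cell-line feature space by CP/PARAFAC tensor
    decomposition or a late-integration autoencoder, selects IC50-associated
    potential mediator genes with L1-regularized regression, and extracts
    the most influential transcription-factor-to-sub-pathway regulatory
    paths from a time-bounded network by labeled influence maximization
    under the independent-cascade model. Ships a synthetic-data generator
    with planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
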