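Package: dmslandscape
Title: Combined Mutational Landscapes and Amino Acid Subtypes from Deep
    Mutational Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to combine heterogeneous deep mutational scanning (DMS)
    studies onto a common enrichment-ratio (ER) scale, assemble the combined
    mutational landscape of protein positions (PCA and UMAP views), cluster
    the positions of each amino acid into functional subtypes with a hybrid
    dynamic tree cut, and project positions from new studies onto a stored
    reference landscape. A synthetic-study generator with planted position
    archetypes makes every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    Biostrings,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Proteomics, Clustering, DimensionReduction
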